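#' Run the PORH analysis pipeline end-to-end
#'
#' Orchestrates cohort generation, (optionally) image simulation and
#' reconstruction, segmentation, biomarker extraction and group statistics,
#' writing CSV/JSON (and TIFF, in image mode) artifacts plus a run manifest.
#' Identical configuration and seeds give byte-identical CSV outputs.
#'
#' @param config A named list, or path to a YAML file, with entries:
#' \describe{
#'   \item{out_dir}{Output directory (created if needed). Required.}
#'   \item{seed}{Integer master seed. Required.}
#'   \item{mode}{`"profile"` (default) or `"image"`.}
#'   \item{protocol}{`"long"` (default) or `"short"`.}
#'   \item{frame_interval}{Seconds, default 1.}
#'   \item{groups}{Character vector of preset names from
#'     [cohort_presets()] (default `c("smoker", "nonsmoker")`).}
#'   \item{layers}{Layers to analyze, default `c("DV", "SD", "RD")`.}
#'   \item{n_subjects}{Override of the presets' cohort size.}
#'   \item{noise_sd}{Profile noise sd, default 0.02.}
#'   \item{image}{Image-mode block: `nx`, `nz`, `dx_um`, `dz_um`,
#'     `noise_sd`, `write_tiff` (default TRUE), `lag_s` (optional deep-layer
#'     time-to-peak advance, seconds).}
#' }
#' @return Invisibly, a list with `biomarkers` (data.frame), `comparisons`
#'   (data.frame or NULL), `manifest`, and in image mode `frames_info`.
#' @export
run_porh_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  if (is.null(config$seed)) stop("config must give an explicit seed")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  mode <- config$mode %||% "profile"
  prot_name <- config$protocol %||% "long"
  fi <- config$frame_interval %||% 1
  protocol <- porh_protocol(prot_name, frame_interval = fi)
  groups <- config$groups %||% c("smoker", "nonsmoker")
  layers <- config$layers %||% c("DV", "SD", "RD")
  noise_sd <- config$noise_sd %||% 0.02
  seed <- as.integer(config$seed)
  presets <- cohort_presets()
  unknown <- setdiff(groups, names(presets))
  if (length(unknown)) stop("unknown group preset(s): ",
                            paste(unknown, collapse = ", "))
  stages <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  result <- list()
  if (mode == "profile") {
    bm_rows <- stage("cohorts+biomarkers", {
      rows <- list()
      for (gi in seq_along(groups)) {
        preset <- presets[[groups[gi]]]
        n <- config$n_subjects %||% preset$n_subjects
        for (li in seq_along(layers)) {
          co <- generate_cohort(preset, layers[li], protocol, noise_sd,
                                seed = seed + 101L * gi + li, n = n)
          for (s in seq_len(n)) {
            fit <- porh_fit(co$profiles[[s]])
            cf <- coef(fit)
            rows[[length(rows) + 1L]] <- data.frame(
              subject_id = co$truths$subject_id[s], group = groups[gi],
              layer = layers[li], MVB = cf[["MVB"]], MVIC = cf[["MVIC"]],
              PIV = cf[["PIV"]], MVC = cf[["MVC"]], HR_pct = cf[["HR_pct"]],
              TP_min = cf[["TP_min"]],
              mvc_true = co$truths$mvc_true[s],
              hr_true_pct = 100 * co$truths$hr_true[s],
              tp_true_min = co$truths$tp_true[s])
          }
        }
      }
      do.call(rbind, rows)
    })
    utils::write.csv(bm_rows, file.path(out, "biomarkers.csv"),
                     row.names = FALSE)
    result$biomarkers <- bm_rows
    if (length(groups) >= 2) {
      cmp <- stage("group_statistics", {
        rows <- list()
        for (ly in layers) for (v in c("MVC", "HR_pct", "TP_min")) {
          a <- bm_rows[bm_rows$group == groups[1] & bm_rows$layer == ly, v]
          b <- bm_rows[bm_rows$group == groups[2] & bm_rows$layer == ly, v]
          gc_ <- compare_groups(a, b, labels = groups[1:2])
          rows[[length(rows) + 1L]] <- data.frame(
            layer = ly, biomarker = v,
            mean_a = gc_$mean[1], sd_a = gc_$sd[1],
            mean_b = gc_$mean[2], sd_b = gc_$sd[2],
            test = gc_$test, p_value = gc_$p_value,
            significant = gc_$significant)
        }
        do.call(rbind, rows)
      })
      utils::write.csv(cmp, file.path(out, "comparisons.csv"),
                       row.names = FALSE)
      jsonlite::write_json(cmp, file.path(out, "comparisons.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      result$comparisons <- cmp
    }
  } else if (mode == "image") {
    imcfg <- config$image %||% list()
    preset <- presets[[groups[1]]]
    lag_min <- (imcfg$lag_s %||% 0) / 60
    pars <- stage("simulate", {
      l <- preset$layers
      sd_tp <- l$SD$tp[1]; rd_tp <- max(l$RD$tp[1] - lag_min, 1e-3)
      list(SD = hemodynamic_params(l$SD$mvc[1], l$SD$hr[1], sd_tp),
           RD = hemodynamic_params(l$RD$mvc[1], l$RD$hr[1], rd_tp))
    })
    series <- stage("forward_model",
      simulate_frame_series(pars, protocol,
                            noise_sd = imcfg$noise_sd %||% 0.01,
                            seed = seed))
    grid <- recon_grid(nx = imcfg$nx %||% 64, nz = imcfg$nz %||% 128,
                       dx_um = imcfg$dx_um %||%
                         (diff(range(series$positions_um)) / (imcfg$nx %||% 64)),
                       dz_um = imcfg$dz_um %||% 10,
                       x0_um = min(series$positions_um))
    frames <- stage("reconstruct", reconstruct_frames(series, grid))
    flat <- stage("segment", {
      base_n <- max(1L, sum(series$t_min < protocol$t_baseline_end))
      base <- frames[[1]]
      if (base_n > 1) {
        acc <- Reduce(`+`, lapply(frames[seq_len(base_n)],
                                  function(f) f$data)) / base_n
        base <- recon_image(acc, grid)
      }
      surf <- detect_surface(base)
      lapply(frames, flatten, surface = surf)
    })
    bounds <- stage("layer_bounds", segment_layers(flat[[1]]))
    profs <- stage("profiles",
      layer_profile(flat, bounds, protocol, normalize = TRUE))
    bm_rows <- stage("biomarkers", {
      do.call(rbind, lapply(c("SD", "RD", "DV"), function(ly) {
        cf <- coef(porh_fit(profs[[ly]]))
        data.frame(subject_id = "phantom", group = groups[1], layer = ly,
                   MVB = cf[["MVB"]], MVIC = cf[["MVIC"]], PIV = cf[["PIV"]],
                   MVC = cf[["MVC"]], HR_pct = cf[["HR_pct"]],
                   TP_min = cf[["TP_min"]])
      }))
    })
    utils::write.csv(bm_rows, file.path(out, "biomarkers.csv"),
                     row.names = FALSE)
    prof_df <- do.call(rbind, lapply(names(profs), function(ly)
      data.frame(layer = ly, t_min = profs[[ly]]$t_min,
                 intensity = profs[[ly]]$intensity)))
    utils::write.csv(prof_df, file.path(out, "profiles.csv"),
                     row.names = FALSE)
    write_layer_bounds(bounds, file.path(out, "layer_bounds.json"))
    if (isTRUE(imcfg$write_tiff %||% TRUE))
      stage("render", write_recon_tiff(flat, file.path(out, "frames.tiff")))
    result$biomarkers <- bm_rows
    result$frames_info <- list(n_frames = length(frames),
                               grid = unclass(grid)[c("nx", "nz", "dx_um", "dz_um")])
  } else stop("mode must be 'profile' or 'image'")

  manifest <- list(
    package = "porhmeso",
    version = as.character(utils::packageVersion("porhmeso")),
    r_version = as.character(getRversion()),
    mode = mode, protocol = prot_name, frame_interval_s = fi,
    groups = groups, layers = layers, noise_sd = noise_sd, seed = seed,
    stages = stages, timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}
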