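# End-to-end orchestration: contours (simulated or from files) -> EFD ->
# PCA -> group statistics, with optional rendered-channel measurements and
# track kinematics, written as a reproducible TSV/JSON report bundle.

#' Run the full morphometry pipeline
#'
#' Two input modes, selected by the config:
#' * simulation mode: `config$groups` is a list of group descriptions
#'   (label, n, head-parameter means/SDs, optional vacuole/acrosome
#'   rendering and track parameters); everything is generated by the
#'   synthetic-data module with known ground truth;
#' * file mode: `config$contours` names a contour CSV
#'   ([read_contours()] dialect) and `config$manifest` a TSV with columns
#'   `specimen_id` and `group`.
#'
#' The pipeline computes normalized EFD coefficient vectors (H harmonics),
#' fits pooled covariance PCA, scores every specimen, reconstructs mean
#' shapes at 0 and +/- `sd_multiple` score SDs per component, runs
#' control-anchored comparisons on each PC (plus acrosome area, vacuole
#' prevalence and kinematics when available), and writes the tables to
#' `out_dir`.
#'
#' @param config list or path to a JSON config. Recognized fields:
#'   `groups`/`contours`+`manifest`, `control` (default first group),
#'   `H` (default 20), `n_components` (default 2), `n_points` (256),
#'   `sd_multiple` (2), `seed` (1), `render` (logical; render channels and
#'   measure vacuoles/acrosomes in simulation mode), `tracks_per_group`
#'   (0), `out_dir` (NULL = nothing written), `comparison_method`
#'   (`"dunnett"`).
#' @return Invisibly, a `pipeline_report` list: `coefficients`, `pca`,
#'   `scores`, `mean_shapes`, `measurements`, `kinematics`, `comparisons`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(H = 20L, n_components = 2L, n_points = 256L, sd_multiple = 2,
         seed = 1L, render = FALSE, tracks_per_group = 0L,
         out_dir = NULL, comparison_method = "dunnett",
         canonical_chirality = FALSE),
    config)

  # ---- assemble contours and group labels -------------------------------
  sim_pops <- NULL
  if (!is.null(cfg$groups)) {
    sim_pops <- lapply(seq_along(cfg$groups), function(i) {
      g <- cfg$groups[[i]]
      spec <- population_spec(
        label = g$label, n = g$n,
        params = do.call(head_params,
                         g$params %||% list()),
        sd = g$sd %||% list(),
        seed = (cfg$seed * 131L + i) %% .Machine$integer.max)
      list(spec = spec, raw = g,
           members = make_population(spec, n_points = cfg$n_points))
    })
    contours <- unlist(lapply(sim_pops, function(p)
      stats::setNames(lapply(p$members, `[[`, "contour"),
                      vapply(p$members, `[[`, character(1), "specimen_id"))),
      recursive = FALSE)
    manifest <- data.frame(
      specimen_id = names(contours),
      group = rep(vapply(sim_pops, function(p) p$spec$label, character(1)),
                  vapply(sim_pops, function(p) length(p$members), integer(1))))
  } else if (!is.null(cfg$contours) && !is.null(cfg$manifest)) {
    contours <- read_contours(cfg$contours)
    manifest <- utils::read.delim(cfg$manifest, stringsAsFactors = FALSE)
    if (!all(c("specimen_id", "group") %in% names(manifest)))
      stop("manifest must have columns specimen_id and group", call. = FALSE)
    unmatched <- c(setdiff(names(contours), manifest$specimen_id),
                   setdiff(manifest$specimen_id, names(contours)))
    if (length(unmatched))
      stop("manifest/contour mismatch for specimen(s): ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    contours <- contours[manifest$specimen_id]
  } else {
    stop("config needs either 'groups' (simulation mode) or 'contours' + ",
         "'manifest' (file mode)", call. = FALSE)
  }
  control <- cfg$control %||% manifest$group[1L]

  # ---- EFD + PCA --------------------------------------------------------
  mat <- coefficient_matrix(contours, H = cfg$H,
                            canonical_chirality = cfg$canonical_chirality)
  model <- fit_shape_pca(mat, n_components = cfg$n_components)
  scores <- pca_scores(model, mat,
                       group = manifest$group[match(rownames(mat),
                                                    manifest$specimen_id)])

  shapes <- list()
  for (k in seq_len(cfg$n_components))
    for (m in c(-cfg$sd_multiple, 0, cfg$sd_multiple))
      shapes[[sprintf("PC%d_%+g_sd", k, m)]] <-
        mean_shape(model, k, m, n_points = cfg$n_points)

  comparisons <- list()
  pc_cols <- grep("^PC", names(scores), value = TRUE)
  for (pc in pc_cols) {
    gr <- split(scores[[pc]], scores$group)
    comparisons[[pc]] <- compare_to_control(gr, control,
                                            method = cfg$comparison_method)
  }

  # ---- optional rendered measurements (simulation mode) -----------------
  measurements <- NULL
  if (isTRUE(cfg$render) && !is.null(sim_pops)) {
    rows <- list()
    for (p in sim_pops) {
      rs <- do.call(render_spec, p$raw$render %||% list())
      for (j in seq_along(p$members)) {
        mem <- p$members[[j]]
        img <- render_head_image(mem$contour, rs,
                                 seed = (p$spec$seed + j) %% .Machine$integer.max)
        ac <- acrosome_area(img$channels$acrosome, img$head_mask,
                            pixel_size = rs$pixel_size)
        vc <- detect_vacuoles(img$channels$nuclear, img$head_mask)
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = mem$specimen_id, group = p$spec$label,
          acrosome_area_um2 = ac$area_um2,
          head_area_um2 = ac$head_area_um2,
          vacuole_count = vc$count)
      }
    }
    measurements <- do.call(rbind, rows)
    gr <- split(measurements$acrosome_area_um2, measurements$group)
    if (all(lengths(gr) >= 2L))
      comparisons$acrosome_area <-
        compare_to_control(gr, control, method = cfg$comparison_method)
  }

  # ---- optional synthetic kinematics ------------------------------------
  kinematics <- NULL
  if (cfg$tracks_per_group > 0L && !is.null(sim_pops)) {
    rows <- list()
    for (pi in seq_along(sim_pops)) {
      p <- sim_pops[[pi]]
      tp <- p$raw$track %||% list()
      base_speed <- tp$speed %||% 100
      speed_sd <- tp$speed_sd %||% 15
      speeds <- with_seed((cfg$seed * 977L + pi) %% .Machine$integer.max,
                          pmax(stats::rnorm(cfg$tracks_per_group,
                                            base_speed, speed_sd), 0))
      for (j in seq_len(cfg$tracks_per_group)) {
        tr <- make_track("sinusoid", speed = speeds[j],
                         amplitude = tp$amplitude %||% 4,
                         frequency = tp$frequency %||% 8,
                         duration = tp$duration %||% 1,
                         frame_rate = tp$frame_rate %||% 60)
        ks <- summarize_track(tr)
        rows[[length(rows) + 1L]] <- data.frame(
          track_id = sprintf("%s_trk%03d", p$spec$label, j),
          group = p$spec$label, VSL = ks$VSL, VCL = ks$VCL, VAP = ks$VAP,
          motile = ks$motile)
      }
    }
    kinematics <- do.call(rbind, rows)
    for (v in c("VSL", "VCL", "VAP")) {
      gr <- split(kinematics[[v]], kinematics$group)
      if (all(lengths(gr) >= 2L))
        comparisons[[v]] <- compare_to_control(gr, control,
                                               method = cfg$comparison_method)
    }
  }

  report <- list(coefficients = mat, pca = model, scores = scores,
                 mean_shapes = shapes, measurements = measurements,
                 kinematics = kinematics, comparisons = comparisons,
                 config = cfg)
  class(report) <- "pipeline_report"

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report bundle to disk
#'
#' Produces `coefficients.tsv` (specimen_id + a1..dH), `pc_scores.tsv`,
#' `mean_shapes.csv` (contour CSV of the 0 / +/- SD reconstructions),
#' `measurements.tsv` and `kinematics.tsv` when present,
#' `comparisons.tsv`, and `summary.json` + `summary.txt`.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file)
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)

  coef_df <- data.frame(specimen_id = rownames(report$coefficients),
                        report$coefficients, check.names = FALSE)
  tsv(coef_df, "coefficients.tsv")
  tsv(report$scores, "pc_scores.tsv")
  write_contours(file.path(out_dir, "mean_shapes.csv"), report$mean_shapes)
  if (!is.null(report$measurements)) tsv(report$measurements,
                                         "measurements.tsv")
  if (!is.null(report$kinematics)) tsv(report$kinematics, "kinematics.tsv")

  comp <- do.call(rbind, lapply(names(report$comparisons), function(v)
    as_comparison_table(report$comparisons[[v]], v)))
  tsv(comp, "comparisons.tsv")
  write_shape_pca(report$pca, file.path(out_dir, "pca_model.json"))

  summary_list <- list(
    n_specimens = nrow(report$coefficients),
    H = report$pca$H,
    var_explained = report$pca$var_explained,
    control = report$comparisons[[1L]]$control,
    comparison_method = report$comparisons[[1L]]$method,
    comparisons = lapply(report$comparisons, function(gc)
      stats::setNames(as.list(gc$comparisons$letter), gc$comparisons$group)))
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- c(
    sprintf("spermshape pipeline report (%d specimens, H = %d)",
            nrow(report$coefficients), report$pca$H),
    sprintf("variance explained: %s",
            paste(sprintf("PC%d %.1f%%", seq_along(report$pca$var_explained),
                          100 * report$pca$var_explained), collapse = ", ")),
    sprintf("control group: %s (%s comparisons; a p<0.05, b p<0.01, c p<0.001)",
            summary_list$control, summary_list$comparison_method),
    unlist(lapply(names(report$comparisons), function(v) {
      gc <- report$comparisons[[v]]
      sprintf("  %s: %s", v,
              paste(sprintf("%s p=%.3g %s", gc$comparisons$group,
                            gc$comparisons$p_value,
                            ifelse(gc$comparisons$letter == "", "ns",
                                   gc$comparisons$letter)),
                    collapse = "; "))
    })))
  writeLines(txt, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("spermshape pipeline report: %d specimens, H = %d\n",
              nrow(x$coefficients), x$pca$H))
  print(x$pca)
  for (v in names(x$comparisons)) {
    cat("--", v, "--\n")
    print(x$comparisons[[v]])
  }
  invisible(x)
}
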