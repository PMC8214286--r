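# Orchestration: configuration, end-to-end runs over files, evaluation and
# clinical summaries, provenance records. The command-line entry point in
# inst/cli/lacine is a thin wrapper around these functions.

#' Default pipeline configuration
#'
#' Nested configuration with every tunable of the pipeline. Values can be
#' overridden by a (partial) JSON file via [load_config()] or by passing a
#' modified list to the pipeline functions.
#'
#' @param overrides optional nested list merged over the defaults.
#' @return Nested configuration list.
#' @export
la_config <- function(overrides = NULL) {
  cfg <- list(
    gmm = list(tol = 1e-6, max_iter = 200L, seed = 0L, per_frame = TRUE),
    polar = list(delta_r = 0.25, delta_theta = 1,
                 angular_span_2ch = 180, angular_span_4ch = 233,
                 radial_factor = 2, la_side = "auto"),
    canny = list(sigma = 2, low_frac = 0.1, high_frac = 0.2,
                 edge_cost = 0, bg_cost = 1),
    snake = list(alpha = 0.02, beta = 0.0002, max_step = 24L),
    post = list(prominence_frac = 0.15, kernel_theta = 5L, kernel_time = 3L,
                mean_theta = 5L))
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Load configuration from a JSON file
#'
#' @param path JSON file holding a partial configuration (same nesting as
#'   [la_config()]); `NULL` returns the defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(la_config())
  la_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

.provenance <- function(config, extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  c(list(package = "lacine",
         version = as.character(utils::packageVersion("lacine")),
         r_version = R.version.string,
         config = config,
         config_md5 = unname(tools::md5sum(tmp)),
         timestamp = format(Sys.time(), tz = "UTC")), extra)
}

#' Segment a cine from files
#'
#' Reads a cine and its valve annotations, runs [segment_cine()], and
#' writes the masks (NIfTI), the contour polygons (JSON), a per-frame log
#' (CSV: threshold, grid sizes, snake energy, edge fraction), and a
#' provenance record.
#'
#' @param cine_path NIfTI or TIFF cine.
#' @param mv_path JSON/CSV valve points.
#' @param view `"2ch"` or `"4ch"`.
#' @param out_dir output directory (created if missing).
#' @param config configuration list, see [la_config()].
#' @param spacing_override optional `c(dy, dx)` mm for headerless inputs.
#' @return The [la_segmentation()], invisibly.
#' @export
run_segment <- function(cine_path, mv_path, view, out_dir,
                        config = la_config(), spacing_override = NULL) {
  cine <- read_cine(cine_path, spacing_override = spacing_override,
                    view = view)
  ann <- read_mv_points(mv_path, cine$frame_count,
                        image_shape = dim(cine$frames)[1:2])
  seg <- segment_cine(cine, ann, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_masks(seg, file.path(out_dir, "masks.nii.gz"),
              contours_path = file.path(out_dir, "contours.json"))
  d <- seg$diagnostics
  log_df <- data.frame(frame = seq_len(seg$frame_count) - 1L,
                       threshold = d$threshold, n_r = d$n_r,
                       n_theta = d$n_theta, energy = d$energy,
                       edge_fraction = d$edge_fraction,
                       low_confidence = d$low_confidence)
  utils::write.csv(log_df, file.path(out_dir, "frames.csv"),
                   row.names = FALSE)
  prov <- .provenance(config, list(cine = cine_path, mv = mv_path,
                                   view = view,
                                   spacing = cine$pixel_spacing))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(seg)
}

#' Evaluate predicted masks against a reference from files
#'
#' @param pred_path,ref_path mask stacks readable by [read_masks()].
#' @param spacing `c(dy, dx)` mm/pixel.
#' @param out_csv destination for the per-frame table; the mean +/- SD
#'   summary goes to a sibling `*_summary.csv`.
#' @return The per-frame `data.frame`, invisibly.
#' @export
run_evaluate <- function(pred_path, ref_path, spacing, out_csv) {
  pred <- read_masks(pred_path); ref <- read_masks(ref_path)
  res <- evaluate_segmentation(pred, ref, spacing)
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res, out_csv, row.names = FALSE)
  utils::write.csv(attr(res, "summary"),
                   sub("\\.csv$", "_summary.csv", out_csv),
                   row.names = FALSE)
  invisible(res)
}

#' Clinical metrics from two segmentation output directories
#'
#' Reads the masks and contours written by [run_segment()] for a paired
#' 2ch/4ch study and writes the per-frame volume/strain curves plus the
#' EDV/ESV/EF/GLS summary.
#'
#' @param dir_2ch,dir_4ch [run_segment()] output directories.
#' @param spacing_2ch,spacing_4ch per-view `c(dy, dx)` mm/pixel.
#' @param out_csv destination for the per-frame table; the scalar summary
#'   goes to a sibling `*_summary.csv`.
#' @return The [clinical_metrics()] list, invisibly.
#' @export
run_clinical <- function(dir_2ch, dir_4ch, spacing_2ch, spacing_4ch,
                         out_csv) {
  s2 <- read_masks(file.path(dir_2ch, "masks.nii.gz"),
                   contours_path = file.path(dir_2ch, "contours.json"))
  s4 <- read_masks(file.path(dir_4ch, "masks.nii.gz"),
                   contours_path = file.path(dir_4ch, "contours.json"))
  cm <- clinical_metrics(s2, s4, spacing_2ch, spacing_4ch)
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(frame = seq_along(cm$volume_ml) - 1L,
                              volume_ml = cm$volume_ml,
                              strain_pct = cm$strain_pct),
                   out_csv, row.names = FALSE)
  utils::write.csv(data.frame(edv_ml = cm$edv, esv_ml = cm$esv,
                              ef_pct = cm$ef, gls_pct = cm$gls),
                   sub("\\.csv$", "_summary.csv", out_csv),
                   row.names = FALSE)
  invisible(cm)
}

#' Write a phantom study to disk
#'
#' Writes, per view, the cine (NIfTI), valve points (JSON), ground-truth
#' masks and contours, and the analytic truth tables.
#'
#' @param phantom a [phantom_generate()] result.
#' @param out_dir destination directory.
#' @return `out_dir`, invisibly.
#' @export
write_phantom <- function(phantom, out_dir) {
  for (vn in names(phantom$views)) {
    v <- phantom$views[[vn]]
    d <- file.path(out_dir, vn)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_cine(v$cine, file.path(d, "cine.nii.gz"))
    write_mv_points(v$annotation, file.path(d, "mv_points.json"))
    write_masks(v$truth, file.path(d, "truth_masks.nii.gz"),
                contours_path = file.path(d, "truth_contours.json"))
    utils::write.csv(v$truth_frames, file.path(d, "truth_frames.csv"),
                     row.names = FALSE)
  }
  tr <- phantom$truth
  utils::write.csv(data.frame(frame = seq_along(tr$volume_ml) - 1L,
                              volume_ml = tr$volume_ml,
                              strain_pct = tr$strain_pct),
                   file.path(out_dir, "truth_curves.csv"), row.names = FALSE)
  utils::write.csv(data.frame(edv_ml = tr$edv, esv_ml = tr$esv,
                              ef_pct = tr$ef, gls_pct = tr$gls),
                   file.path(out_dir, "truth_summary.csv"), row.names = FALSE)
  invisible(out_dir)
}
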