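#' Write and read event / feature tables
#'
#' Delimited text with a header, full double precision. Sample indices are
#' written 0-based with times in seconds alongside; they are restored to
#' 1-based on reading.
#'
#' @param events data frame (any event or feature table).
#' @param path output file.
#' @return `path`, invisibly; `read_event_table()` returns the data frame.
#' @export
write_event_table <- function(events, path) {
  out <- events
  for (col in intersect(c("peak", "onset", "offset"), names(out)))
    out[[col]] <- out[[col]] - 1L     # 0-based on disk
  utils::write.table(format(out, digits = 17, scientific = NA,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in intersect(c("peak", "onset", "offset"), names(out)))
    out[[col]] <- out[[col]] + 1L
  out
}

#' Write and read a waveform cloud container
#'
#' The event x sample matrix is stored as tab-delimited text at full
#' precision with a JSON sidecar (`<path>.json`) holding sampling rate,
#' window, z-scoring provenance and the per-event metadata table.
#'
#' @param cloud a `ripple_cloud`.
#' @param path output file for the matrix.
#' @return `path` invisibly; `read_cloud()` returns the `ripple_cloud`.
#' @export
write_cloud <- function(cloud, path) {
  utils::write.table(format(cloud$X, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(rate = cloud$rate, halfwidth_ms = cloud$halfwidth_ms,
               dropped = cloud$dropped %||% 0L, meta = cloud$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cloud
#' @export
read_cloud <- function(path) {
  X <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(X) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(X = X, rate = meta$rate, halfwidth_ms = meta$halfwidth_ms,
                 meta = as.data.frame(meta$meta), dropped = meta$dropped),
            class = "ripple_cloud")
}

#' Run the synthetic analysis pipeline end to end
#'
#' Orchestrates the stages in dependency order on a synthetic laminar
#' session: simulate, detect, features, cloud, topology (H0), embedding,
#' Structure Index, decoding. Intermediate artifacts are written under
#' `out_dir` together with a JSON manifest (configuration snapshot, seed,
#' per-stage row counts) sufficient to re-run deterministic stages
#' bit-compatibly.
#'
#' @param config list; recognized entries: `n_events`, `threshold_sd`
#'   (must lie in 2-5), `noise_sd`, `d`, `n_bins`, `si_k`, `stages`
#'   (character subset of the defaults, in order).
#' @param out_dir output directory (created).
#' @param seed RNG seed for every stochastic stage.
#' @return list of per-stage results, with the manifest in `$manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ripplemap_"),
                         seed = 1) {
  stages_all <- c("simulate", "detect", "features", "cloud", "topo",
                  "embed", "si", "decode")
  stages <- config$stages %||% stages_all
  stopifnot(all(stages %in% stages_all))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- detection_config(threshold_sd = config$threshold_sd %||% 3)
  counts <- list()
  res <- list()

  set.seed(seed)
  sess <- generate_laminar_session(n_events = config$n_events %||% 150,
                                   noise_sd = config$noise_sd %||% 0.05,
                                   seed = seed)
  res$simulate <- sess
  counts$simulated <- nrow(sess$events)
  write_event_table(sess$events, file.path(out_dir, "ground_truth.tsv"))

  if ("detect" %in% stages) {
    det <- detect_ripples(sess$recording, cfg, sp_channel = 3)
    res$detect <- det
    counts$detected <- nrow(det$events)
    write_event_table(det$events, file.path(out_dir, "events.tsv"))
  }
  if ("features" %in% stages) {
    feats <- event_features(sess$recording, res$detect$events, sp_channel = 3,
                            sr_channel = 5, cfg = cfg)
    res$features <- feats
    counts$features <- nrow(feats)
    counts$dropped_feature_events <- attr(feats, "dropped")
    write_event_table(feats, file.path(out_dir, "features.tsv"))
  }
  if ("cloud" %in% stages) {
    ev_ok <- res$detect$events[res$detect$events$peak %in% res$features$peak, ]
    cl <- build_waveform_matrix(res$detect$filtered, ev_ok,
                                rate = sess$recording$rate)
    res$cloud <- cl
    counts$cloud_rows <- nrow(cl$X)
    counts$cloud_dropped <- cl$dropped
    write_cloud(cl, file.path(out_dir, "cloud.tsv"))
  }
  if ("topo" %in% stages) {
    bc <- persistence_barcodes(res$cloud, maxdim = 0, seed = seed)[[1]]
    res$topo <- list(barcode = bc, betti = betti_numbers(bc),
                     abid = abid_dimension(res$cloud,
                                           k = min(50, nrow(res$cloud$X) - 1)))
  }
  if ("embed" %in% stages) {
    res$embed <- reduce_embedding(res$cloud, method = "pca",
                                  d = config$d %||% 4, seed = seed)
  }
  if ("si" %in% stages) {
    res$si <- si_table(res$embed$coords, res$features["frequency"],
                       n_bins = config$n_bins %||% 10,
                       k = config$si_k, n_shuffles = 20, seed = seed)
    utils::write.table(res$si, file.path(out_dir, "si.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if ("decode" %in% stages) {
    # match detected events to ground truth by peak proximity
    gt_idx <- vapply(res$features$peak, function(p)
      which.min(abs(sess$events$peak - p)), 0L)
    res$decode <- train_csd_decoder(res$embed$coords,
                                    sess$csd_true[gt_idx, , drop = FALSE],
                                    space = "feature", folds = 5,
                                    model = "wiener", seed = seed)
  }

  manifest <- list(seed = seed, config = config,
                   threshold_sd = cfg$threshold_sd, stages = stages,
                   counts = counts,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  res
}
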