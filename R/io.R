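# Plain-text readers and writers for the pipeline's interchange
# formats: COP and stabilometer traces with a `# fs=` header, delimited
# EEG with a montage-label header row, square connectivity TSVs with
# JSON sidecars, tree edge lists, tidy metric tables, and YAML study
# configurations.

read_fs_header <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs\\s*=\\s*([0-9.]+)", first))[[1]]
  if (length(m) < 2L)
    abort_param(paste0("expected a '# fs=<Hz>' header line in ", path))
  as.numeric(m[2])
}

#' Write / read a COP trial as delimited text
#'
#' Two tab-separated columns (`ap`, `ml`, cm) preceded by a
#' `# fs=<Hz>` header line.
#'
#' @param trial a [cop_trial()].
#' @param path output file.
#' @return `write_cop` the path invisibly; `read_cop` a [cop_trial()].
#' @export
write_cop <- function(trial, path) {
  stopifnot(inherits(trial, "cop_trial"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", trial$fs), con)
  utils::write.table(data.frame(ap = trial$ap, ml = trial$ml), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cop
#' @export
read_cop <- function(path) {
  fs <- read_fs_header(path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  if (!all(c("ap", "ml") %in% names(d)))
    abort_param("COP file must have 'ap' and 'ml' columns")
  cop_trial(d$ap, d$ml, fs)
}

#' Write / read a one-column angle trace (degrees) with `# fs=` header
#'
#' @param x numeric series in degrees.
#' @param fs sampling rate, Hz.
#' @param path file path.
#' @return `write_angle_trace` the path invisibly; `read_angle_trace` a
#'   list with `x` and `fs`.
#' @export
write_angle_trace <- function(x, fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", fs), con)
  utils::write.table(data.frame(angle = x), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_angle_trace
#' @export
read_angle_trace <- function(path) {
  fs <- read_fs_header(path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  list(x = d[[1]], fs = fs)
}

#' Write / read an EEG recording as delimited text
#'
#' One column per channel with a header row of montage labels, preceded
#' by a `# fs=<Hz>` line. Periocular channels, when present, are stored
#' as extra columns named `EOG.supra`, `EOG.infra`, `EOG.left`,
#' `EOG.right`.
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @return `write_eeg_txt` the path invisibly; `read_eeg_txt` an
#'   [eeg_recording()]. Channel labels are matched case-insensitively
#'   against the montage on read.
#' @export
write_eeg_txt <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  d <- as.data.frame(t(rec$data))
  names(d) <- rec$labels
  if (!is.null(rec$eog)) {
    e <- as.data.frame(t(rec$eog))
    names(e) <- paste0("EOG.", rownames(rec$eog))
    d <- cbind(d, e)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec$fs), con)
  utils::write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eeg_txt
#' @export
read_eeg_txt <- function(path) {
  fs <- read_fs_header(path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                         check.names = FALSE)
  is_eog <- grepl("^EOG\\.", names(d))
  eog <- NULL
  if (any(is_eog)) {
    eog <- t(as.matrix(d[, is_eog, drop = FALSE]))
    rownames(eog) <- sub("^EOG\\.", "", names(d)[is_eog])
  }
  labels <- names(d)[!is_eog]
  canon <- montage_1020()
  hit <- match(tolower(labels), tolower(canon))
  labels[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  eeg_recording(t(as.matrix(d[, !is_eog, drop = FALSE])), fs,
                labels = labels, eog = eog)
}

#' Serialize an epoch set to a binary container with a JSON sidecar
#'
#' Samples are written as little-endian doubles (channel-major per
#' epoch); band label, sampling rate, shape, channel labels and the
#' rejection mask go to `<path>.json`.
#'
#' @param eps an [epoch_set()].
#' @param path path of the binary container; the sidecar adds `.json`.
#' @return `save_epoch_set` the path invisibly; `load_epoch_set` an
#'   [epoch_set()].
#' @export
save_epoch_set <- function(eps, path) {
  stopifnot(inherits(eps, "epoch_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  for (e in eps$epochs) writeBin(as.numeric(e), con, size = 8L, endian = "little")
  meta <- list(fs = eps$fs, band = eps$band, labels = eps$labels,
               n_epochs = length(eps$epochs),
               n_channels = nrow(eps$epochs[[1]]),
               n_samples = ncol(eps$epochs[[1]]),
               mask = eps$mask)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_epoch_set
#' @export
load_epoch_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  per <- meta$n_channels * meta$n_samples
  eps <- lapply(seq_len(meta$n_epochs), function(k) {
    matrix(readBin(con, "double", per, size = 8L, endian = "little"),
           meta$n_channels, meta$n_samples)
  })
  epoch_set(eps, meta$fs, meta$labels, meta$band,
            mask = as.data.frame(meta$mask))
}

#' Write a connectivity matrix as a labeled square TSV with sidecar
#'
#' @param cm a [connectivity_matrix_obj()].
#' @param path TSV path; the JSON sidecar (method, band, epoch id) adds
#'   `.json`.
#' @return the path, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(cm$w, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  jsonlite::write_json(list(method = cm$method, band = cm$band,
                            epoch_id = cm$epoch_id, n_nodes = nrow(cm$w)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  w <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  connectivity_matrix_obj(w, meta$method, meta$band, meta$epoch_id)
}

#' Export a spanning tree
#'
#' Edge list as TSV (`from`, `to`, `weight` using node labels) and,
#' optionally, a parenthesized single-line rendering for quick viewing.
#'
#' @param t a [spanning_tree()].
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
write_tree <- function(t, path) {
  stopifnot(inherits(t, "spanning_tree"))
  utils::write.table(data.frame(from = t$nodes[t$edges$i],
                                to = t$nodes[t$edges$j],
                                weight = t$edges$weight),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree
#' @export
format_tree <- function(t) {
  adj <- tree_adjacency(t)
  seen <- rep(FALSE, length(t$nodes))
  render <- function(v) {
    seen[v] <<- TRUE
    kids <- adj[[v]][!seen[adj[[v]]]]
    if (!length(kids)) return(t$nodes[v])
    paste0("(", paste(vapply(kids, render, character(1L)), collapse = ","),
           ")", t$nodes[v])
  }
  paste0(render(1L), ";")
}

#' Append tidy metric rows to a TSV
#'
#' Writes (or appends to) a tab-separated table, one row per
#' subject/session/trial with metric columns, the exchange format
#' between pipeline stages.
#'
#' @param df data frame of metric rows.
#' @param path TSV path.
#' @param append append without header if the file exists.
#' @return the path, invisibly.
#' @export
write_metrics_tsv <- function(df, path, append = FALSE) {
  header <- !(append && file.exists(path))
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = header,
                       append = !header)
  )
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @export
read_metrics_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
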