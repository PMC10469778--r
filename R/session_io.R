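#' Read a session recording from a fixture directory
#'
#' Loads the plain-text fixture layout written by [write_session_fixture()]
#' and validates its schema: `meta.json` must declare the sampling rate,
#' channel counts and channel sets; `annotations.csv` must contain strictly
#' ordered, non-overlapping `start_s`, `cv_s`, `end_s` triples plus a
#' `label`; `csep.csv` must match the declared matrix dimensions.
#'
#' @param path Fixture directory.
#' @return An object of class `"ecog_session"`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no such fixture directory: ", path, call. = FALSE)
  meta_file <- file.path(path, "meta.json")
  ann_file <- file.path(path, "annotations.csv")
  csep_file <- file.path(path, "csep.csv")
  for (f in c(meta_file, ann_file, csep_file)) {
    if (!file.exists(f)) stop("fixture is missing ", basename(f), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  need <- c("sample_rate_hz", "n_channels", "n_samples", "smc_indices")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("fixture schema error: meta.json lacks ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ann <- as.data.frame(data.table::fread(ann_file))
  need_ann <- c("start_s", "cv_s", "end_s", "label")
  miss <- setdiff(need_ann, names(ann))
  if (length(miss)) {
    stop("fixture schema error: annotations lack ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  times <- as.vector(t(as.matrix(ann[, c("start_s", "cv_s", "end_s")])))
  if (nrow(ann) && any(diff(times) <= 0)) {
    stop("annotation times must be strictly increasing within and across ",
         "trials", call. = FALSE)
  }
  m <- data.table::fread(csep_file)
  if (nrow(m) != meta$n_samples || ncol(m) != meta$n_channels) {
    stop("fixture schema error: csep matrix is ", nrow(m), "x", ncol(m),
         " but meta declares ", meta$n_samples, "x", meta$n_channels,
         call. = FALSE)
  }
  dur <- meta$n_samples / meta$sample_rate_hz
  if (nrow(ann) && (min(times) < 0 || max(times) > dur)) {
    stop("annotation times fall outside the recording", call. = FALSE)
  }
  inv <- meta$invalid_intervals
  if (is.null(inv) || length(inv) == 0 ||
      (is.data.frame(inv) && nrow(inv) == 0)) {
    inv <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  inv <- as.data.frame(inv)
  structure(list(
    subject_id = meta$subject_id %||% "unknown",
    session_id = meta$session_id %||% basename(path),
    sample_rate_hz = meta$sample_rate_hz,
    csep = t(as.matrix(m)),
    annotations = ann,
    invalid_intervals = inv,
    smc_indices = as.integer(meta$smc_indices),
    bad_indices = as.integer(meta$bad_indices %||% integer(0))
  ), class = "ecog_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select valid sensorimotor channels
#'
#' Removes the session's bad channels from its sensorimotor (SMC) channel
#' set, preserving the original ordering: per-session bad lists override the
#' collection-level SMC list.
#'
#' @param session An `"ecog_session"`, or a list with `smc_indices` and
#'   `bad_indices`.
#' @return Integer vector of surviving channel indices (the valid SMC set,
#'   `N_channels` = its length).
#' @examples
#' select_channels(list(smc_indices = c(1, 2, 3, 4), bad_indices = 3))
#' @export
select_channels <- function(session) {
  smc <- as.integer(session$smc_indices)
  bad <- as.integer(session$bad_indices)
  if (length(smc) == 0) stop("empty SMC channel set", call. = FALSE)
  if (anyDuplicated(smc)) stop("SMC indices must be unique", call. = FALSE)
  keep <- smc[!(smc %in% bad)]
  if (length(keep) == 0) {
    stop("degenerate session: every SMC channel is marked bad", call. = FALSE)
  }
  keep
}

#' Common average reference
#'
#' Subtracts the per-sample mean across channels from every channel, so the
#' cross-channel mean of the output is identically zero. Applied after bad
#' channels have been excluded, over the valid SMC channels only.
#'
#' @param x Channels-by-samples numeric matrix with at least two rows.
#' @return Matrix of the same shape.
#' @examples
#' common_average_reference(rbind(c(1, 1), c(3, 3)))
#' @export
common_average_reference <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2) {
    stop("common average reference needs a matrix with >= 2 channels ",
         "(a single channel would be zeroed)", call. = FALSE)
  }
  sweep(x, 2, colMeans(x), "-")
}
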