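# Session IO: the CSV + JSON manifest dialect, rating binarization, cutting
# waveforms into 128-frame chunks, and the session-level 80/10/10 split.

#' Binarize a 1-9 affect rating
#'
#' Ratings 1-4 map to `"low"`, 5-9 to `"high"` (threshold at the scale
#' midpoint 4.5; integer ratings never tie).
#'
#' @param rating Integer rating(s) in 1..9. Non-integer or out-of-range
#'   ratings are rejected.
#' @return Character vector of `"low"` / `"high"`.
#' @export
binarize_rating <- function(rating) {
  if (any(!is.finite(rating)) || any(rating != as.integer(rating)) ||
      any(rating < 1) || any(rating > 9)) {
    stop("binarize_rating: ratings must be integers in 1..9")
  }
  ifelse(rating <= 4, "low", "high")
}

#' Cut a waveform into non-overlapping 128-frame chunks
#'
#' Chunk `i` (0-based) covers samples `[chunk_len * i, chunk_len * (i + 1))`;
#' any trailing remainder shorter than one chunk is dropped.
#'
#' @param waveform Numeric vector (>= `chunk_len` samples).
#' @param chunk_len Samples per chunk (default 128, about 4 s at 30 Hz).
#' @return A `T x chunk_len` matrix, one chunk per row.
#' @export
chunk_waveform <- function(waveform, chunk_len = 128L) {
  n <- length(waveform)
  if (n < chunk_len) {
    stop("chunk_waveform: waveform has ", n, " samples; at least ",
         chunk_len, " are required for one chunk")
  }
  T <- n %/% chunk_len
  matrix(waveform[seq_len(T * chunk_len)], nrow = T, ncol = chunk_len,
         byrow = TRUE)
}

#' Assign train/val/test split tags to a manifest
#'
#' Session-level random split. Validation and test sizes are
#' `round(fraction * N)` (half-up); the training set takes the remainder.
#' Assignment is by a seeded shuffle of the session ids, so the split is
#' reproducible and forms a partition.
#'
#' @param manifest Manifest data.frame with a `session_id` column.
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return The manifest with its `split` column filled in.
#' @export
split_manifest <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("split_manifest: fractions must sum to 1")
  N <- nrow(manifest)
  if (N < 3) stop("split_manifest: need at least 3 sessions")
  n_val <- round_half_up(fractions[2] * N)
  n_test <- round_half_up(fractions[3] * N)
  n_train <- N - n_val - n_test
  if (n_train < 1) stop("split_manifest: rounding left the training set empty")
  set.seed(seed)
  ord <- sample.int(N)
  split <- character(N)
  split[ord[seq_len(n_val)]] <- "val"
  split[ord[n_val + seq_len(n_test)]] <- "test"
  split[ord[(n_val + n_test + 1):N]] <- "train"
  manifest$split <- split
  manifest
}

#' Write a dataset to a directory
#'
#' One two-column CSV (`time_s`, `bvp`) per session, a `manifest.json` array
#' and, when saliency masks are present, a parallel `saliency.json` keyed by
#' session id. Waveform samples are written with 6 decimal places.
#'
#' @param dataset A `pm_dataset` (see [generate_dataset()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_len(nrow(man))) {
    id <- man$session_id[i]
    w <- dataset$waveforms[[id]]
    df <- data.frame(time_s = sprintf("%.6f", (seq_along(w) - 1) / man$fs[i]),
                     bvp = sprintf("%.6f", w))
    utils::write.csv(df, file.path(dir, man$file[i]), row.names = FALSE,
                     quote = FALSE)
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(dataset$masks)) {
    jsonlite::write_json(dataset$masks, file.path(dir, "saliency.json"),
                         auto_unbox = FALSE)
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Verifies that each waveform file holds exactly the `n_samples` promised by
#' the manifest.
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `pm_dataset` list (masks present only if `saliency.json` exists).
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("read_dataset: no manifest at ", man_path)
  man <- jsonlite::fromJSON(man_path)
  waveforms <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) stop("read_dataset: missing waveform file ", path)
    df <- utils::read.csv(path)
    if (nrow(df) != man$n_samples[i]) {
      stop("read_dataset: ", man$session_id[i], " has ", nrow(df),
           " samples but the manifest promises ", man$n_samples[i])
    }
    waveforms[[i]] <- df$bvp
  }
  names(waveforms) <- man$session_id
  masks <- NULL
  sal_path <- file.path(dir, "saliency.json")
  if (file.exists(sal_path)) {
    masks <- jsonlite::fromJSON(sal_path, simplifyVector = TRUE)
    masks <- lapply(masks, as.integer)
  }
  structure(list(manifest = man, waveforms = waveforms, masks = masks),
            class = "pm_dataset")
}

#' Fetch one session record from a dataset
#'
#' @param dataset A `pm_dataset`.
#' @param session_id Session id to look up.
#' @return List with `session_id`, `waveform`, `rating_arousal`,
#'   `rating_valence` and `split`.
#' @export
get_session <- function(dataset, session_id) {
  man <- dataset$manifest
  i <- match(session_id, man$session_id)
  if (is.na(i)) stop("get_session: unknown session_id '", session_id, "'")
  list(session_id = session_id,
       waveform = dataset$waveforms[[session_id]],
       rating_arousal = man$rating_arousal[i],
       rating_valence = man$rating_valence[i],
       split = man$split[i])
}
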