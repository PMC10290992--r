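# Cine series container: an ordered stack of complex-valued image frames with
# cardiac phase labels. The unit of training and ground-truth data.

#' Construct a cine series
#'
#' @param frames complex array N x N x M (or a list of N x N matrices).
#' @param phase_labels integer cardiac phase per frame, 1-based, in
#'   `[1, period_T]`.
#' @param period_T integer number of phases per cardiac cycle.
#' @param pixel_scale arbitrary intensity scale (bookkeeping only).
#' @param is_training flag marking a fully sampled training cycle.
#' @return an object of class `cine_series`.
#' @export
cine_series <- function(frames, phase_labels, period_T,
                        pixel_scale = 1, is_training = FALSE) {
  if (is.list(frames)) {
    N <- nrow(frames[[1]])
    frames <- array(unlist(frames), dim = c(N, N, length(frames)))
  }
  if (length(dim(frames)) != 3L || dim(frames)[1] != dim(frames)[2])
    stop("frames must be an N x N x M array")
  storage.mode(frames) <- "complex"
  M <- dim(frames)[3]
  phase_labels <- as.integer(phase_labels)
  period_T <- as.integer(period_T)
  if (M < 1L) stop("need at least one frame")
  if (length(phase_labels) != M) stop("one phase label per frame required")
  if (any(phase_labels < 1L | phase_labels > period_T))
    stop("phase labels must lie in [1, period_T]")
  structure(list(frames = frames, phase_labels = phase_labels,
                 period_T = period_T, pixel_scale = pixel_scale,
                 is_training = isTRUE(is_training)),
            class = "cine_series")
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_series> %d frames of %dx%d, period_T=%d%s\n",
              d[3], d[1], d[2], x$period_T,
              if (x$is_training) " (training)" else ""))
  invisible(x)
}

n_frames <- function(cine) dim(cine$frames)[3]
grid_size <- function(cine) dim(cine$frames)[1]

cine_frame <- function(cine, i) cine$frames[, , i]

# Frames as an N^2 x M matrix of row-major vectorized columns.
frames_matrix <- function(cine) {
  N <- grid_size(cine); M <- n_frames(cine)
  matrix(vapply(seq_len(M), function(i) vec_img(cine$frames[, , i]),
                complex(N * N)), N * N, M)
}

#' Decimate a training cycle in time
#'
#' Keeps frames at the original phases 1, 1+V, 1+2V, ... and relabels them
#' as coarse phases 1..ceil(T/V). Emulates a training scan acquired at 1/V
#' of the test temporal resolution.
#'
#' @param train a training `cine_series`.
#' @param V integer decimation factor (V = 1 is the identity).
#' @return a `cine_series` with `ceiling(T/V)` frames; the original (fine)
#'   phase of each retained frame is kept in attribute `fine_phase`, and the
#'   factor in attribute `temporal_factor`.
#' @export
decimate_training <- function(train, V) {
  stopifnot(inherits(train, "cine_series"))
  V <- as.integer(V)
  if (V < 1L) stop("V must be >= 1")
  if (V == 1L) return(train)
  T <- train$period_T
  if (V >= T) stop("decimation factor must be smaller than the period")
  keep <- seq(1L, T, by = V)
  out <- cine_series(train$frames[, , keep, drop = FALSE],
                     phase_labels = seq_along(keep),
                     period_T = length(keep),
                     pixel_scale = train$pixel_scale,
                     is_training = train$is_training)
  attr(out, "fine_phase") <- train$phase_labels[keep]
  attr(out, "temporal_factor") <- V
  out
}

#' Rescale test frames to reference mean magnitudes
#'
#' Each frame is multiplied by a real positive scalar so that its mean
#' magnitude equals that of the reference frame: the training frame with the
#' same phase label when one exists, otherwise the previous (already
#' rescaled) test frame. Pixel phase is preserved. Protects against
#' frame-to-frame contrast variations such as automated DICOM rescaling.
#'
#' @param test a test `cine_series`.
#' @param train the training `cine_series` providing reference means.
#' @param mode `"train"` (default) matches training counterparts where
#'   available and chains from the previous test frame otherwise;
#'   `"previous"` always chains from the previous frame (the first frame is
#'   matched against training).
#' @return the rescaled `cine_series`.
#' @export
rescale_means <- function(test, train, mode = c("train", "previous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(test, "cine_series"), inherits(train, "cine_series"))
  if (grid_size(test) != grid_size(train)) stop("grid sizes must match")
  ref_phase <- if (!is.null(attr(train, "fine_phase")))
    attr(train, "fine_phase") else train$phase_labels
  train_means <- vapply(seq_len(n_frames(train)),
                        function(i) mean(Mod(train$frames[, , i])), 0)
  out <- test$frames
  prev_mean <- NA_real_
  for (i in seq_len(n_frames(test))) {
    hit <- match(test$phase_labels[i], ref_phase)
    use_train <- !is.na(hit) && (mode == "train" || i == 1L)
    ref <- if (use_train) train_means[hit] else prev_mean
    if (is.na(ref)) stop("no reference available for frame ", i)
    if (ref <= 0) stop("reference frame has zero mean")
    m <- mean(Mod(out[, , i]))
    if (m <= 0) stop("test frame ", i, " has zero mean")
    out[, , i] <- out[, , i] * (ref / m)
    prev_mean <- mean(Mod(out[, , i]))
  }
  cine_series(out, test$phase_labels, test$period_T,
              pixel_scale = test$pixel_scale, is_training = test$is_training)
}
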