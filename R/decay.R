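#' Normalize a transcription-shutoff time course
#'
#' Forms the target/reference signal ratio at every time point and rescales
#' so the pre-shutoff (t = 0) value is 100, removing loading artifacts
#' (any common multiplicative factor cancels exactly).
#'
#' @param times Minutes after transcription block; strictly increasing and
#'   starting at 0.
#' @param target Target-transcript signal (> 0), same length.
#' @param reference Reference-transcript signal (> 0), same length.
#' @return A [DecayTimecourse-class] with
#'   `normalized[i] = 100 * (target[i]/reference[i]) / (target[1]/reference[1])`.
#' @export
normalizeTimecourse <- function(times, target, reference) {
  times <- as.numeric(times)
  target <- as.numeric(target)
  reference <- as.numeric(reference)
  if (length(times) != length(target) || length(times) != length(reference))
    stop("times, target and reference must share length", call. = FALSE)
  if (!length(times) || times[1L] != 0)
    stop("the series must include a t = 0 point first", call. = FALSE)
  if (any(!is.finite(target)) || any(!is.finite(reference)) ||
      any(target <= 0) || any(reference <= 0))
    stop("signals must be finite and strictly positive", call. = FALSE)
  ratio <- target / reference
  new("DecayTimecourse", times = times, target = target,
      reference = reference, normalized = 100 * ratio / ratio[1L])
}

#' Fit one-phase exponential decay
#'
#' Least-squares fit of `Y(t) = 100 * exp(-k t)` to the normalized series,
#' with the initial value pinned at 100 and the plateau at 0, so the decay
#' rate `k` is the only free parameter. The loss is minimized on the
#' normalized (linear) scale; the optimum is located by golden-section
#' search and polished by Newton iterations on the stationarity condition
#' to a relative tolerance of 1e-12 in `k`. A series whose least-squares
#' optimum sits at `k <= 0` (no decay) is flagged `unbounded` with
#' `halfLife = Inf` rather than raising an error.
#'
#' @param tc A [DecayTimecourse-class], or a numeric vector of times when
#'   `normalized` is supplied.
#' @param normalized Optional normalized values (first element 100) when
#'   `tc` is a plain time vector.
#' @return A [HalfLifeFit-class]; `halfLife(fit)` is `log(2)/k` minutes.
#' @examples
#' tc <- normalizeTimecourse(c(0, 60, 120), c(100, 50, 25), rep(1, 3))
#' halfLife(fitOnePhaseDecay(tc))  # 60
#' @export
fitOnePhaseDecay <- function(tc, normalized = NULL) {
  if (methods::is(tc, "DecayTimecourse")) {
    t <- tc@times; y <- tc@normalized
  } else {
    t <- as.numeric(tc); y <- as.numeric(normalized)
  }
  n <- length(t)
  if (n < 3L) stop("need at least three time points", call. = FALSE)
  if (any(!is.finite(y))) stop("normalized values must be finite",
                               call. = FALSE)
  rss <- function(k) sum((y - 100 * exp(-k * t))^2)
  # dRSS/dk and its derivative, for Newton polishing.
  grad <- function(k) {
    e <- exp(-k * t)
    sum(200 * t * e * (y - 100 * e))
  }
  hess <- function(k) {
    e <- exp(-k * t)
    sum(-200 * t^2 * e * (y - 100 * e) + 200 * 100 * t^2 * e^2)
  }
  dt <- min(diff(t))
  kHi <- log(2) / dt * 50  # half-life down to dt/50: generous bracket
  opt <- optimize(rss, interval = c(0, kHi), tol = 1e-12)
  k <- opt$minimum
  # Newton refinement of the stationary point.
  for (it in seq_len(100L)) {
    g <- grad(k); h <- hess(k)
    if (!is.finite(g) || !is.finite(h) || h <= 0) break
    step <- g / h
    kNew <- k - step
    if (kNew <= 0) break
    k <- kNew
    if (abs(step) <= 1e-12 * max(k, 1e-12)) break
  }
  if (k <= 1e-9 && rss(0) <= rss(max(k, 1e-9)) + 1e-12) {
    return(new("HalfLifeFit", k = 0, halfLife = Inf, rss = rss(0),
               nPoints = as.integer(n), unbounded = TRUE))
  }
  new("HalfLifeFit", k = k, halfLife = log(2) / k, rss = rss(k),
      nPoints = as.integer(n), unbounded = FALSE)
}

#' Half-life ratio between two fits
#'
#' @param fitA,fitB [HalfLifeFit-class] objects.
#' @return List with `ratio` (= halfLife(fitA) / halfLife(fitB)) and
#'   `unbounded` (TRUE when either half-life is infinite, in which case
#'   the ratio is not a finite number).
#' @export
compareHalfLives <- function(fitA, fitB) {
  unbounded <- fitA@unbounded || fitB@unbounded
  ratio <- fitA@halfLife / fitB@halfLife
  list(ratio = ratio, unbounded = unbounded)
}
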