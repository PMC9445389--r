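#' Clock-time helpers
#'
#' Clock intervals (within a single day) are represented as two-column
#' matrices of seconds-of-day `[start, end)`, with `0 <= start < end <=
#' 86400`. Intervals that wrap midnight must be supplied as two pieces.
#'
#' @param x a clock string `"HH:MM"` or `"HH:MM:SS"`, or a numeric number
#'   of seconds since midnight (returned unchanged).
#' @return `parse_clock()`: seconds since midnight (numeric).
#' @examples
#' parse_clock("07:00")
#' parse_clock("23:00") - parse_clock("07:00")  # 16 h light period
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- vapply(as.character(x), function(s) {
    parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    if (any(is.na(parts)) || length(parts) < 2 || length(parts) > 3)
      stop("invalid clock time: ", s, call. = FALSE)
    sum(parts * c(3600, 60, 1)[seq_along(parts)])
  }, numeric(1), USE.NAMES = FALSE)
  if (any(out < 0 | out > 86400)) stop("clock time outside 00:00-24:00")
  out
}

#' @rdname parse_clock
#' @param intervals a list of length-2 vectors (start, end), each element a
#'   clock string or seconds-of-day.
#' @return `clock_intervals()`: a 2-column matrix (start_s, end_s), rows
#'   sorted, validated to be disjoint and within the day.
#' @export
clock_intervals <- function(intervals) {
  if (is.matrix(intervals)) {
    m <- intervals
  } else {
    if (length(intervals) == 2L && !is.list(intervals))
      intervals <- list(intervals)
    m <- do.call(rbind, lapply(intervals, function(iv) parse_clock(iv)))
  }
  colnames(m) <- c("start_s", "end_s")
  if (any(m[, 1] >= m[, 2])) stop("interval start must precede end")
  if (any(m < 0) || any(m > 86400)) stop("intervals must lie in 00:00-24:00")
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2]))
    stop("clock intervals overlap")
  m
}

# total seconds of [a1,a2) covered by the union of rows of `iv`
interval_overlap_s <- function(a1, a2, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  sum(pmax(0, pmin(a2, iv[, 2]) - pmax(a1, iv[, 1])))
}

# TRUE for seconds-of-day falling inside any row of `iv`  ([start, end))
in_intervals <- function(sec, iv) {
  hit <- rep(FALSE, length(sec))
  for (k in seq_len(nrow(iv))) hit <- hit | (sec >= iv[k, 1] & sec < iv[k, 2])
  hit
}
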