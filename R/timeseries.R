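#' Population time-series container
#'
#' A `pp_ts` is a long-format data frame of per-patch counts with columns
#' `run_id` (run or experimental round), `patch_id` (0-based), `time`
#' (days), `H` (herbivore count) and `P` (predator count). Counts must be
#' non-negative integers and every `(run_id, patch_id, time)` combination
#' must appear exactly once.
#'
#' @param df a data frame with the required columns (extra columns are kept)
#' @return the validated data frame with class `pp_ts`
#' @export
pp_ts <- function(df) {
  validate_pp_ts(df)
  class(df) <- unique(c("pp_ts", class(df)))
  df
}

validate_pp_ts <- function(df) {
  need <- c("run_id", "patch_id", "time", "H", "P")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("time series is missing columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("H", "P")) {
    v <- df[[col]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf(
        "column %s has negative, missing or non-integer counts at row(s) %s",
        col, paste(utils::head(bad, 5L), collapse = ", ")
      ))
    }
  }
  key <- paste(df$run_id, df$patch_id, df$time, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (run_id, patch_id, time) at row(s) ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  invisible(df)
}

#' Read a population time series from CSV
#'
#' Expects the long format written by [write_timeseries()]: a header
#' `run_id,patch_id,time,H,P` (extra columns are preserved). The file is
#' validated row by row; violations are reported with row indices.
#'
#' @param path CSV file path
#' @return a `pp_ts`
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    df <- data.frame(run_id = integer(0), patch_id = integer(0),
                     time = numeric(0), H = integer(0), P = integer(0))
  }
  pp_ts(df)
}

#' Write a population time series to CSV
#'
#' @param ts a `pp_ts`
#' @param path output path
#' @export
write_timeseries <- function(ts, path) {
  validate_pp_ts(ts)
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

# internal: dense matrix view of a pp_ts.
# Returns N x C integer matrices H and P whose columns are (run, time)
# combinations ordered by run then time, plus the column run/time labels
# and the patch id ordering. Requires a complete grid within each run.
ts_matrices <- function(ts) {
  patches <- sort(unique(ts$patch_id))
  n <- length(patches)
  runs <- unique(ts$run_id)
  cols <- unique(data.frame(run_id = ts$run_id, time = ts$time))
  cols <- cols[order(match(cols$run_id, runs), cols$time), , drop = FALSE]
  c_idx <- match(paste(ts$run_id, ts$time, sep = "\r"),
                 paste(cols$run_id, cols$time, sep = "\r"))
  r_idx <- match(ts$patch_id, patches)
  C <- nrow(cols)
  H <- matrix(NA_real_, n, C)
  P <- matrix(NA_real_, n, C)
  H[cbind(r_idx, c_idx)] <- as.numeric(ts$H)
  P[cbind(r_idx, c_idx)] <- as.numeric(ts$P)
  if (anyNA(H) || anyNA(P)) {
    stop("time series is not a complete (run, patch, time) grid")
  }
  list(H = H, P = P, patches = patches,
       run = cols$run_id, time = cols$time)
}

# internal: back to long format
matrices_to_ts <- function(m) {
  n <- length(m$patches)
  C <- length(m$time)
  pp_ts(data.frame(
    run_id = rep(m$run, each = n),
    patch_id = rep(m$patches, times = C),
    time = rep(m$time, each = n),
    H = as.vector(m$H),
    P = as.vector(m$P)
  ))
}

# internal: indices j of columns such that (j, j+1) is a consecutive
# recorded-time pair within the same run
transition_cols <- function(m) {
  C <- length(m$time)
  if (C < 2L) return(integer(0))
  j <- seq_len(C - 1L)
  j[m$run[j] == m$run[j + 1L]]
}
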