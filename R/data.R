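#' Daily COVID-19 mortality-rate series (France and United Kingdom)
#'
#' Loads one of the two embedded daily mortality-rate series: France
#' (108 days, 1 March - 16 June 2021) or the United Kingdom (82 days,
#' 1 May - 16 July 2021).  Each value is the daily rate proxy
#' `x_i = ND_i / (CC_i - CD_{i-1}) * 1000`, where `ND` is daily new deaths,
#' `CC` cumulative confirmed cases and `CD` cumulative deaths (see
#' [tgl_build_series()]).  Values are stored as plain decimal text, exactly
#' four decimals each, and parsed on load, so checksums are platform-stable.
#'
#' @param label `"france"` or `"uk"`.
#' @return A list of class `"tgl_series"` with `values` (in printed order,
#'   not sorted), `label`, `n`, and `period`.
#' @examples
#' fr <- tgl_covid_data("france")
#' fr$n; head(fr$values)
#' @export
tgl_covid_data <- function(label = c("france", "uk")) {
  label <- match.arg(label)
  file <- system.file("extdata",
                      paste0("covid_", label, ".txt"),
                      package = "tglomax", mustWork = TRUE)
  values <- scan(file, what = numeric(), comment.char = "#", quiet = TRUE)
  periods <- c(france = "2021-03-01 to 2021-06-16",
               uk = "2021-05-01 to 2021-07-16")
  structure(list(values = values, label = label, n = length(values),
                 period = periods[[label]]),
            class = "tgl_series")
}

#' @export
print.tgl_series <- function(x, ...) {
  cat(sprintf("COVID-19 mortality-rate series '%s': %d daily values, %s\n",
              x$label, x$n, x$period))
  invisible(x)
}

#' Published TGL point estimates for the embedded series
#'
#' The five TGL parameter estimates published for the complete-sample fits
#' to the two embedded series, usable to reproduce the published
#' goodness-of-fit comparison without refitting.
#'
#' @param label `"france"` or `"uk"`.
#' @return A [tgl_params()] object.
#' @examples
#' tgl_gof(tgl_covid_data("uk")$values, tgl_published_fit("uk"))
#' @export
tgl_published_fit <- function(label = c("france", "uk")) {
  label <- match.arg(label)
  if (label == "france") {
    tgl_params(delta = 0.2296, gamma = 106.5058, vartheta = 0.1131,
               pi = 8.3588, beta = 0.9078)
  } else {
    tgl_params(delta = 3.7995, gamma = 197.6717, vartheta = 0.0110,
               pi = 0.3759, beta = 0.7269)
  }
}

#' Construct a mortality-rate series from raw daily counts
#'
#' \deqn{x_i = \frac{ND_i}{CC_i - CD_{i-1}} \times 1000,}
#' where `ND` is daily new deaths, `CC` daily cumulative confirmed cases,
#' and `CD` daily cumulative deaths; the previous day's cumulative deaths
#' enter the denominator, so the day-zero value `cd0` must be supplied.
#'
#' @param nd daily new deaths.
#' @param cc daily cumulative cases (same length as `nd`).
#' @param cd daily cumulative deaths (same length as `nd`).
#' @param cd0 cumulative deaths on the day before the series starts.
#' @return Numeric vector of rates; days with zero new deaths yield zeros
#'   and are flagged with a warning (the embedded series contain none).
#' @examples
#' tgl_build_series(nd = 1, cc = 1000, cd = 1, cd0 = 0)
#' @export
tgl_build_series <- function(nd, cc, cd, cd0) {
  stopifnot(length(nd) == length(cc), length(cc) == length(cd),
            length(cd0) == 1L)
  cd_prev <- c(cd0, cd[-length(cd)])
  denom <- cc - cd_prev
  bad <- which(denom <= 0)
  if (length(bad))
    stop("nonpositive denominator (CC_i - CD_{i-1}) at index ", bad[1])
  if (any(nd == 0))
    warning("zero new-death days produce zero rates")
  nd / denom * 1000
}
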