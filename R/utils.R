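#' @import data.table
#' @importFrom stats quantile rbinom rlnorm rnorm runif sd qgamma pgamma
#'   dnbinom optim uniroot glm binomial coef vcov p.adjust pnorm setNames
#'   qnorm integrate rpois rgamma
#' @importFrom utils write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parse FAERS-style dates, allowing partial precision
#'
#' FAERS date fields are YYYYMMDD integers, but partial dates (YYYYMM, YYYY)
#' occur. Partial dates are imputed to a fixed day (YYYYMM to the 15th, YYYY
#' to July 1) and flagged imprecise so downstream analyses can exclude them.
#'
#' @param x character or integer vector of raw date codes.
#' @return A list with `date` (`Date` vector) and `imprecise` (logical).
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "NA"] <- NA_character_
  nc <- nchar(x)
  full <- !is.na(x) & nc == 8L
  ym <- !is.na(x) & nc == 6L
  y <- !is.na(x) & nc == 4L
  out <- rep(as.Date(NA), length(x))
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out[ym] <- as.Date(paste0(x[ym], "15"), format = "%Y%m%d")
  out[y] <- as.Date(paste0(x[y], "0701"), format = "%Y%m%d")
  list(date = out, imprecise = ym | y)
}

format_faers_date <- function(d) format(d, "%Y%m%d")

# Simple condition-free logging: messages unless option pvfaers.quiet is TRUE.
pv_log <- function(fmt, ...) {
  if (!isTRUE(getOption("pvfaers.quiet", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pv <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
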