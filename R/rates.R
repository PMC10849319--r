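#' First-cousin consanguinity rates
#'
#' Bundle of the four per-generation first-cousin mating-pair frequencies, as
#' fractions of all mating pairs. The four types follow the male-ego
#' convention: patrilateral-parallel (`cpp`, the two fathers are brothers),
#' patrilateral-cross (`cpc`, his father and her mother are siblings),
#' matrilateral-parallel (`cmp`, the two mothers are sisters), and
#' matrilateral-cross (`cmc`, his mother and her father are siblings). The
#' total first-cousin rate `c1 = cpp + cpc + cmp + cmc` is always recomputed
#' from the four components, never stored independently.
#'
#' @param cpp,cpc,cmp,cmc Fractions in \[0, 1\]; their sum must not exceed 1.
#' @return An object of class `consang_rates`: a named list with elements
#'   `cpp`, `cpc`, `cmp`, `cmc` and (computed) `c1`.
#' @examples
#' consang_rates(cmp = 0.05)
#' consang_rates() # no consanguinity
#' @export
consang_rates <- function(cpp = 0, cpc = 0, cmp = 0, cmc = 0) {
  r <- c(cpp = cpp, cpc = cpc, cmp = cmp, cmc = cmc)
  if (!is.numeric(r) || length(r) != 4L || anyNA(r)) {
    stop("all four rates must be single non-missing numbers", call. = FALSE)
  }
  if (any(r < 0) || any(r > 1)) {
    stop("each consanguinity rate must lie in [0, 1]", call. = FALSE)
  }
  if (sum(r) > 1 + 1e-12) {
    stop("total first-cousin rate c1 = cpp + cpc + cmp + cmc exceeds 1",
         call. = FALSE)
  }
  structure(list(cpp = cpp, cpc = cpc, cmp = cmp, cmc = cmc,
                 c1 = cpp + cpc + cmp + cmc),
            class = "consang_rates")
}

#' @export
print.consang_rates <- function(x, ...) {
  cat("First-cousin mating-pair rates (fractions):\n")
  cat(sprintf("  patrilateral-parallel (cpp): %.6g\n", x$cpp))
  cat(sprintf("  patrilateral-cross    (cpc): %.6g\n", x$cpc))
  cat(sprintf("  matrilateral-parallel (cmp): %.6g\n", x$cmp))
  cat(sprintf("  matrilateral-cross    (cmc): %.6g\n", x$cmc))
  cat(sprintf("  total                 (c1) : %.6g\n", x$c1))
  invisible(x)
}

as_consang_rates <- function(rates) {
  if (inherits(rates, "consang_rates")) return(rates)
  if (is.numeric(rates) && !is.null(names(rates))) {
    rates <- as.list(rates)
  }
  if (is.list(rates)) {
    known <- intersect(names(rates), c("cpp", "cpc", "cmp", "cmc"))
    return(do.call(consang_rates, rates[known]))
  }
  stop("cannot interpret `rates` as consanguinity rates", call. = FALSE)
}

#' Read a table of per-population first-cousin mating rates
#'
#' Reads a TSV/CSV with columns `population`, `cpp`, `cpc`, `cmp`, `cmc`. The
#' rate columns are expected as percentages of all mating pairs (the usual
#' reporting convention of demographic surveys) and are divided by 100.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` uses a comma, anything else a tab).
#' @param percent If `TRUE` (default) rate columns are percentages and are
#'   converted to fractions.
#' @return A tibble with columns `population`, `cpp`, `cpc`, `cmp`, `cmc`
#'   (fractions) and `c1`.
#' @export
read_rates_table <- function(path, percent = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  need <- c("population", "cpp", "cpc", "cmp", "cmc")
  if (!all(need %in% names(d))) {
    stop("rates table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(d[need])
  if (percent) {
    d[c("cpp", "cpc", "cmp", "cmc")] <-
      lapply(d[c("cpp", "cpc", "cmp", "cmc")], function(x) x / 100)
  }
  # validate each row through the constructor
  for (i in seq_len(nrow(d))) {
    consang_rates(d$cpp[i], d$cpc[i], d$cmp[i], d$cmc[i])
  }
  d$c1 <- d$cpp + d$cpc + d$cmp + d$cmc
  d
}

#' First-cousin mating rates for nine Jewish populations
#'
#' Demographic survey estimates of the four first-cousin mating-type
#' frequencies (fractions of all mating pairs) for nine populations, shipped
#' with the package as a plain-text fixture. These are the standard inputs
#' for the per-population theoretical X:A sharing-ratio ranges.
#'
#' @return A tibble as returned by [read_rates_table()].
#' @examples
#' first_cousin_rates()
#' @export
first_cousin_rates <- function() {
  read_rates_table(system.file("extdata", "first_cousin_rates.tsv",
                               package = "xaroh", mustWork = TRUE))
}
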