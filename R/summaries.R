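# Segment-table summarization: per-population mean genomic proportions of
# ROH and IBD, with the field's normalization conventions (female-only X
# ROH; haplotype-pair weighting of X IBD totals; fixed genome lengths).

#' Genome lengths used for normalization
#'
#' Totals by which summed segment lengths are divided to obtain genomic
#' proportions. The defaults are the GRCh37 physical lengths in megabases
#' (chromosomes 1-22 combined, and X). For segment tables in centimorgans,
#' supply genetic-map totals with `unit = "cM"`.
#'
#' @param autosomal,x Total lengths.
#' @param unit `"Mb"` or `"cM"`; must match the segment table being
#'   summarized (the two are never silently interconverted).
#' @export
genome_lengths <- function(autosomal = 2881.03, x = 155.27,
                           unit = c("Mb", "cM")) {
  unit <- match.arg(unit)
  stopifnot(autosomal > 0, x > 0)
  structure(list(autosomal = autosomal, x = x, unit = unit),
            class = "genome_lengths")
}

#' Build a segment table
#'
#' A segment table records ROH calls (one carrier) or IBD calls (an
#' unordered pair of carriers) as total-length records. Lengths are
#' positive, in a single unit for the whole table.
#'
#' @param population,kind,chrom,id1,id2,length Vectors of equal length:
#'   population label; `"roh"` or `"ibd"`; `"autosomal"` or `"x"`;
#'   carrier id(s) (`id2` is `NA` for ROH); segment length > 0.
#' @param unit `"cM"` or `"Mb"`, stored as an attribute.
#' @return A tibble of class `segment_table`.
#' @export
segment_table <- function(population, kind, chrom, id1, id2 = NA_character_,
                          length, unit = c("cM", "Mb")) {
  unit <- match.arg(unit)
  d <- tibble::tibble(population = as.character(population),
                      kind = as.character(kind),
                      chrom = as.character(chrom),
                      id1 = as.character(id1),
                      id2 = as.character(id2),
                      length = as.numeric(length))
  validate_segment_table(d)
  attr(d, "unit") <- unit
  class(d) <- c("segment_table", class(d))
  d
}

validate_segment_table <- function(d) {
  if (nrow(d) == 0) return(invisible(d))
  stopifnot(all(d$kind %in% c("roh", "ibd")),
            all(d$chrom %in% c("autosomal", "x")))
  if (any(d$length <= 0)) stop("segment lengths must be positive", call. = FALSE)
  ibd <- d$kind == "ibd"
  if (any(ibd & (is.na(d$id2) | d$id2 == d$id1))) {
    stop("IBD records need two distinct carrier ids", call. = FALSE)
  }
  if (any(!ibd & !is.na(d$id2))) {
    stop("ROH records must not carry a second id", call. = FALSE)
  }
  invisible(d)
}

segment_unit <- function(segments) {
  u <- attr(segments, "unit")
  if (is.null(u)) stop("segment table has no length unit", call. = FALSE)
  u
}

check_meta <- function(segments, meta) {
  stopifnot(all(c("id", "population", "sex") %in% names(meta)))
  if (anyDuplicated(meta$id)) stop("duplicate ids in metadata", call. = FALSE)
  if (!all(meta$sex %in% c("male", "female"))) {
    stop("metadata sex must be 'male' or 'female'", call. = FALSE)
  }
  carriers <- unique(c(segments$id1, segments$id2))
  carriers <- carriers[!is.na(carriers)]
  missing <- setdiff(carriers, meta$id)
  if (length(missing) > 0) {
    stop("segment carriers absent from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  invisible(meta)
}

#' Drop duplicated segment records
#'
#' Removes records that are identical after normalizing the carrier-pair
#' order, as arise for X-chromosomal IBD when male genotypes were coded
#' pseudodiploid before phasing.
#'
#' @param segments A segment table.
#' @export
dedupe_segments <- function(segments) {
  swap <- !is.na(segments$id2) & segments$id2 < segments$id1
  tmp <- segments$id1[swap]
  segments$id1[swap] <- segments$id2[swap]
  segments$id2[swap] <- tmp
  dplyr::distinct(segments)
}

#' Per-population mean ROH genomic proportion
#'
#' For each population and chromosome class, sums ROH lengths over all
#' eligible individuals, divides by the number of eligible individuals (all
#' individuals for the autosomes; females only for the X, since males carry
#' a single X), and normalizes by the genome length. Populations with no
#' females get an `NA` X proportion and are reported with a message.
#'
#' @param segments A segment table containing only `kind == "roh"` records.
#' @param meta Cohort metadata: tibble with columns `id`, `population`,
#'   `sex`.
#' @param lengths A [genome_lengths()] object in the same unit as
#'   `segments`.
#' @return Tibble with columns `population`, `n_individuals`, `n_females`,
#'   `roh_autosomal`, `roh_x`.
#' @export
summarize_roh <- function(segments, meta, lengths = genome_lengths()) {
  validate_segment_table(segments)
  if (nrow(segments) > 0 && !all(segments$kind == "roh")) {
    stop("`segments` must contain only ROH records", call. = FALSE)
  }
  if (segment_unit(segments) != lengths$unit) {
    stop("segment table unit (", segment_unit(segments),
         ") does not match genome lengths unit (", lengths$unit, ")",
         call. = FALSE)
  }
  check_meta(segments, meta)
  check_population_match(segments, meta)

  sex_of <- stats::setNames(meta$sex, meta$id)
  bad_x <- segments$chrom == "x" & sex_of[segments$id1] == "male"
  if (any(bad_x)) {
    warning(sum(bad_x), " male X ROH record(s) dropped", call. = FALSE)
    segments <- segments[!bad_x, ]
  }

  counts <- meta |>
    dplyr::group_by(population) |>
    dplyr::summarise(n_individuals = dplyr::n(),
                     n_females = sum(sex == "female"), .groups = "drop")
  totals <- segments |>
    dplyr::group_by(population, chrom) |>
    dplyr::summarise(total = sum(length), .groups = "drop")

  out <- counts
  get_total <- function(pop, ch) {
    v <- totals$total[totals$population == pop & totals$chrom == ch]
    if (length(v) == 0) 0 else v
  }
  out$roh_autosomal <- vapply(seq_len(nrow(out)), function(i) {
    get_total(out$population[i], "autosomal") /
      out$n_individuals[i] / lengths$autosomal
  }, numeric(1))
  out$roh_x <- vapply(seq_len(nrow(out)), function(i) {
    if (out$n_females[i] == 0) return(NA_real_)
    get_total(out$population[i], "x") / out$n_females[i] / lengths$x
  }, numeric(1))
  if (anyNA(out$roh_x)) {
    message("no females in: ",
            paste(out$population[is.na(out$roh_x)], collapse = ", "),
            "; X ROH proportion unavailable")
  }
  out
}

check_population_match <- function(segments, meta) {
  if (nrow(segments) == 0) return(invisible())
  pop_of <- stats::setNames(meta$population, meta$id)
  bad1 <- pop_of[segments$id1] != segments$population
  bad2 <- !is.na(segments$id2) & pop_of[segments$id2] != segments$population
  if (any(bad1 | bad2, na.rm = TRUE)) {
    stop("segment population label disagrees with carrier metadata ",
         "(IBD pairs may not span populations)", call. = FALSE)
  }
  invisible()
}

#' Per-population mean IBD genomic proportion
#'
#' For each unordered pair of individuals, the total IBD length is divided
#' by the number of cross-individual haplotype pairs compared — 4 on the
#' autosomes; on the X, 1 for a male-male pair, 2 for male-female, 4 for
#' female-female — and by the genome length. The population value is the
#' mean of this proportion over all pairs of individuals in the population,
#' pairs with no called sharing included.
#'
#' @param segments A segment table containing only `kind == "ibd"` records.
#' @inheritParams summarize_roh
#' @return Tibble with columns `population`, `n_individuals`, `n_pairs`,
#'   `ibd_autosomal`, `ibd_x`.
#' @export
summarize_ibd <- function(segments, meta, lengths = genome_lengths()) {
  validate_segment_table(segments)
  if (nrow(segments) > 0 && !all(segments$kind == "ibd")) {
    stop("`segments` must contain only IBD records", call. = FALSE)
  }
  if (segment_unit(segments) != lengths$unit) {
    stop("segment table unit does not match genome lengths unit",
         call. = FALSE)
  }
  check_meta(segments, meta)
  check_population_match(segments, meta)

  sex_of <- stats::setNames(meta$sex, meta$id)
  hap_pairs <- function(sex1, sex2, ch) {
    if (ch == "autosomal") return(4)
    n1 <- if (sex1 == "female") 2 else 1
    n2 <- if (sex2 == "female") 2 else 1
    n1 * n2
  }

  pops <- sort(unique(meta$population))
  res <- lapply(pops, function(pop) {
    ids <- meta$id[meta$population == pop]
    n <- length(ids)
    n_pairs <- if (n >= 2) choose(n, 2) else 0
    seg <- segments[segments$population == pop, ]
    means <- vapply(c("autosomal", "x"), function(ch) {
      if (n_pairs == 0) return(NA_real_)
      s <- seg[seg$chrom == ch, ]
      if (nrow(s) == 0) return(0)
      key <- paste(pmin(s$id1, s$id2), pmax(s$id1, s$id2))
      tot <- tapply(s$length, key, sum)
      prop <- vapply(names(tot), function(k) {
        pair <- strsplit(k, " ", fixed = TRUE)[[1]]
        w <- hap_pairs(sex_of[pair[1]], sex_of[pair[2]], ch)
        tot[[k]] / w / if (ch == "x") lengths$x else lengths$autosomal
      }, numeric(1))
      sum(prop) / n_pairs
    }, numeric(1))
    tibble::tibble(population = pop, n_individuals = n, n_pairs = n_pairs,
                   ibd_autosomal = means[["autosomal"]],
                   ibd_x = means[["x"]])
  })
  dplyr::bind_rows(res)
}

#' Combined per-population sharing summary
#'
#' Runs [summarize_roh()] and [summarize_ibd()] on the ROH and IBD records
#' of one segment table and joins the results.
#'
#' @param segments A segment table with both kinds of records.
#' @inheritParams summarize_roh
#' @export
population_summary <- function(segments, meta, lengths = genome_lengths()) {
  roh <- segments[segments$kind == "roh", ]
  ibd <- segments[segments$kind == "ibd", ]
  attr(roh, "unit") <- attr(segments, "unit")
  attr(ibd, "unit") <- attr(segments, "unit")
  dplyr::full_join(summarize_roh(roh, meta, lengths),
                   summarize_ibd(ibd, meta, lengths),
                   by = c("population", "n_individuals"))
}

#' Empirical and theoretical X:autosome sharing-ratio table
#'
#' Combines per-population empirical X:A ratios of mean sharing proportions
#' with the theoretical (min, max) range of the model ratio over a range of
#' population sizes, computed from each population's consanguinity rates.
#'
#' @param summary Output of [population_summary()] (or compatible tibble).
#' @param rates_table A tibble as from [first_cousin_rates()] /
#'   [read_rates_table()]; only populations present in both tables are
#'   kept (others are dropped with a message).
#' @param u Minimum segment length in centimorgans for the theoretical
#'   ratios (default 0.1).
#' @param n_min,n_max Population-size range scanned (default 500-50000).
#' @return Tibble with empirical `roh_ratio`, `ibd_ratio` and theoretical
#'   `roh_theory_min/max`, `ibd_theory_min/max` per population.
#' @export
ratio_table <- function(summary, rates_table = first_cousin_rates(),
                        u = 0.1, n_min = 500, n_max = 50000) {
  keep <- intersect(summary$population, rates_table$population)
  dropped <- setdiff(summary$population, keep)
  if (length(dropped) > 0) {
    message("populations without consanguinity rates dropped: ",
            paste(dropped, collapse = ", "))
  }
  emp_ratio <- function(x, a, pop, what) {
    if (is.na(x) || is.na(a)) return(NA_real_)
    if (a == 0) {
      warning(what, " ratio undefined for ", pop,
              " (zero autosomal proportion)", call. = FALSE)
      return(NA_real_)
    }
    x / a
  }
  rows <- lapply(keep, function(pop) {
    s <- summary[summary$population == pop, ]
    r <- rates_table[rates_table$population == pop, ]
    rates <- consang_rates(r$cpp, r$cpc, r$cmp, r$cmc)
    th_roh <- ratio_range_over_N(rates, u, n_min, n_max, "roh")
    th_ibd <- ratio_range_over_N(rates, u, n_min, n_max, "ibd")
    tibble::tibble(
      population = pop,
      roh_ratio = emp_ratio(s$roh_x, s$roh_autosomal, pop, "ROH"),
      roh_theory_min = th_roh[["min"]], roh_theory_max = th_roh[["max"]],
      ibd_ratio = emp_ratio(s$ibd_x, s$ibd_autosomal, pop, "IBD"),
      ibd_theory_min = th_ibd[["min"]], ibd_theory_max = th_ibd[["max"]])
  })
  out <- dplyr::bind_rows(rows)
  no_x <- out$population[is.na(out$roh_ratio)]
  if (length(no_x) > 0) {
    message("populations lacking X ROH data: ", paste(no_x, collapse = ", "))
  }
  out
}

#' Read and write segment tables and cohort metadata
#'
#' Plain TSV serialization. `write_segment_table()` adds a `unit` column;
#' `read_segment_table()` requires it to be constant and restores it as the
#' table attribute. `read_segment_bed()` reads a BED-like TSV (`chrom`,
#' `start`, `end` in 0-based half-open base pairs, `carriers` as one id or
#' two comma-separated ids, `population`, `kind`) and converts lengths to
#' megabases.
#'
#' @param segments A segment table.
#' @param path File path.
#' @name segment_io
#' @export
write_segment_table <- function(segments, path) {
  d <- as.data.frame(segments)
  d$unit <- segment_unit(segments)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname segment_io
#' @export
read_segment_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("population", "kind", "chrom", "id1", "id2", "length",
                  "unit") %in% names(d)))
  unit <- unique(d$unit)
  if (length(unit) != 1) stop("mixed units in segment table", call. = FALSE)
  segment_table(d$population, d$kind, d$chrom, d$id1, d$id2, d$length,
                unit = unit)
}

#' @rdname segment_io
#' @export
read_segment_bed <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "carriers", "population",
                  "kind") %in% names(d)))
  if (any(d$end <= d$start)) stop("BED intervals must have end > start",
                                  call. = FALSE)
  ids <- strsplit(d$carriers, ",", fixed = TRUE)
  segment_table(d$population, d$kind,
                ifelse(d$chrom %in% c("X", "chrX"), "x", "autosomal"),
                vapply(ids, `[`, "", 1),
                vapply(ids, function(x) if (length(x) > 1) x[2] else NA_character_, ""),
                (d$end - d$start) / 1e6, unit = "Mb")
}

#' @rdname segment_io
#' @param meta Cohort metadata tibble (`id`, `population`, `sex`).
#' @export
write_cohort_metadata <- function(meta, path) {
  write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname segment_io
#' @export
read_cohort_metadata <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "population", "sex") %in% names(d)))
  tibble::as_tibble(d)
}
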