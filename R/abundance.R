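#' Construct a species abundance sample
#'
#' An abundance sample is the unit of data for the neutrality test: the
#' per-species counts of a local community (or census sample) of fixed total
#' size `J`. It is stored as a tibble with one row per species, sorted in
#' decreasing abundance.
#'
#' @param counts Positive integer abundances, one per species, or a data
#'   frame with columns `species` and `count`.
#' @param species Optional species labels (defaults to rank order).
#' @param metadata Named list of provenance information (generating model,
#'   parameters, seeds, ...) carried along with the sample.
#'
#' @return A tibble of class `abundance_sample` with columns `species` and
#'   `count`, attribute `J` (total individuals) and attribute `metadata`.
#' @examples
#' d <- abundance_sample(c(4, 3, 1))
#' summary_stats(d)
#' @export
abundance_sample <- function(counts, species = NULL, metadata = list()) {
  if (is.data.frame(counts)) {
    if (!all(c("species", "count") %in% names(counts))) {
      abort("data-frame input needs columns 'species' and 'count'")
    }
    species <- counts$species
    counts <- counts$count
  }
  counts <- as.numeric(counts)
  if (!length(counts)) abort("an abundance sample needs at least one species")
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    abort("abundances must be positive integers")
  }
  counts <- as.integer(round(counts))
  if (is.null(species)) species <- seq_along(counts)
  if (length(species) != length(counts)) {
    abort("'species' and 'counts' must have the same length")
  }
  ord <- order(counts, decreasing = TRUE)
  out <- tibble::tibble(species = species[ord], count = counts[ord])
  attr(out, "J") <- sum(out$count)
  attr(out, "metadata") <- metadata
  class(out) <- c("abundance_sample", class(out))
  out
}

#' @export
print.abundance_sample <- function(x, ...) {
  st <- summary_stats(x)
  cat(sprintf("<abundance_sample>  J = %d, S = %d, Shannon H = %.4f\n",
              st$J, st$S, st$shannon))
  NextMethod()
}

# plain integer counts, descending
sample_counts <- function(d) {
  if (inherits(d, "abundance_sample")) return(sort(as.integer(d$count), decreasing = TRUE))
  if (is.data.frame(d) && "count" %in% names(d)) {
    return(sort(as.integer(d$count), decreasing = TRUE))
  }
  sort(as.integer(d), decreasing = TRUE)
}

#' Species richness and Shannon index of an abundance sample
#'
#' @param d An [abundance_sample()], a data frame with a `count` column, or a
#'   bare vector of counts.
#' @return A one-row tibble with columns `J` (individuals), `S` (species
#'   richness) and `shannon` (Shannon diversity index, natural logarithm).
#' @examples
#' summary_stats(abundance_sample(c(2, 1, 1)))
#' @export
summary_stats <- function(d) {
  n <- sample_counts(d)
  J <- sum(n)
  p <- n / J
  tibble::tibble(J = J, S = length(n), shannon = -sum(p * log(p)))
}

# abundance histogram: number of species with each abundance value, used by
# the sampling-formula prefactor
abundance_phi <- function(counts) {
  tab <- table(counts)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read an abundance sample from a text file
#'
#' Accepts either a single column of counts (one per line) or a two-column
#' tab-separated table `species<TAB>count`. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the file.
#' @return An [abundance_sample()].
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) abort(paste0("no data lines in ", path))
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1 || !ncol %in% c(1L, 2L)) {
    bad <- keep[which(lengths(parts) != lengths(parts)[1])[1]]
    abort(paste0("malformed line ", bad, " in ", path))
  }
  get_num <- function(txt, lineno) {
    v <- suppressWarnings(as.numeric(txt))
    if (any(is.na(v))) abort(paste0("malformed line ", lineno[which(is.na(v))[1]],
                                    " in ", path))
    v
  }
  if (ncol == 1L) {
    counts <- get_num(vapply(parts, `[`, "", 1L), keep)
    species <- seq_along(counts)
  } else {
    species <- vapply(parts, `[`, "", 1L)
    counts <- get_num(vapply(parts, `[`, "", 2L), keep)
  }
  bad <- which(counts < 1 | counts != round(counts))
  if (length(bad)) {
    abort(paste0("invalid abundance on line ", keep[bad[1]], " in ", path,
                 " (counts must be positive integers)"))
  }
  abundance_sample(counts, species = species, metadata = list(source = path))
}

#' Write an abundance sample to a text file
#'
#' @param d An [abundance_sample()].
#' @param path Output path.
#' @param format `"counts"` writes one count per line (descending);
#'   `"tsv"` writes `species<TAB>count`.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(d, path, format = c("counts", "tsv")) {
  format <- match.arg(format)
  n <- sample_counts(d)
  if (format == "counts") {
    writeLines(as.character(n), path)
  } else {
    df <- if (inherits(d, "abundance_sample")) d else abundance_sample(d)
    writeLines(c("# species\tcount", paste(df$species, df$count, sep = "\t")), path)
  }
  invisible(path)
}
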