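#' Metacommunity relative-abundance distributions
#'
#' The metacommunity is the static species pool that supplies immigrants to
#' the local community: species `i` arrives with probability proportional to
#' its relative abundance `P_i`. Two concrete pools are provided, plus a
#' symbolic infinitely diverse even pool.
#'
#' * `meta_logseries()` draws the pool from the continuum logseries (Ewens)
#'   species-frequency density \eqn{f_M(x) = \theta x^{-1} (1-x)^{\theta-1}},
#'   the distribution of relative abundances when sampling an effectively
#'   infinite neutral metacommunity with biodiversity parameter
#'   \eqn{\theta}. Sampling uses the stick-breaking (GEM) representation of
#'   this distribution, truncated at `S_T` species and renormalized; at the
#'   default `S_T = 2000` the truncated tail mass is negligible.
#' * `meta_even()` gives `S_T` species with identical frequency `1/S_T`.
#' * `meta_infinite()` is the \eqn{S_T \to \infty} limit of the even pool:
#'   every immigrant belongs to a species never seen before in the local
#'   community, so immigration acts like a speciation process.
#'
#' @param theta Positive biodiversity parameter of the logseries pool.
#' @param S_T Number of species in the pool.
#' @return A tibble of class `metacommunity` with columns `species` and `p`
#'   (relative abundance, summing to 1), and attributes `kind`
#'   (`"logseries"`, `"even"` or `"infinite_even"`), `theta` and `S_T`.
#'   `meta_infinite()` returns a zero-row table with `S_T = Inf`.
#' @examples
#' set.seed(1)
#' m <- meta_logseries(theta = 50)
#' sum(m$p)
#' @export
meta_logseries <- function(theta, S_T = 2000) {
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) || theta <= 0) {
    abort("'theta' must be a positive number")
  }
  check_ST(S_T)
  v <- rbeta(S_T, 1, theta)
  p <- v * cumprod(c(1, 1 - v[-S_T]))
  p <- pmax(p, .Machine$double.xmin)  # stick-breaking can underflow at huge S_T
  p <- p / sum(p)
  new_metacommunity(p, kind = "logseries", theta = theta, S_T = S_T)
}

#' @rdname meta_logseries
#' @export
meta_even <- function(S_T) {
  check_ST(S_T)
  new_metacommunity(rep(1 / S_T, S_T), kind = "even", S_T = S_T)
}

#' @rdname meta_logseries
#' @export
meta_infinite <- function() {
  new_metacommunity(numeric(0), kind = "infinite_even", S_T = Inf)
}

check_ST <- function(S_T) {
  if (!is.numeric(S_T) || length(S_T) != 1 || !is.finite(S_T) ||
      S_T < 1 || S_T != round(S_T)) {
    abort("'S_T' must be a positive integer")
  }
  invisible(S_T)
}

new_metacommunity <- function(p, kind, theta = NA_real_, S_T) {
  out <- tibble::tibble(species = seq_along(p), p = p)
  attr(out, "kind") <- kind
  attr(out, "theta") <- theta
  attr(out, "S_T") <- S_T
  class(out) <- c("metacommunity", class(out))
  out
}

#' @export
print.metacommunity <- function(x, ...) {
  cat(sprintf("<metacommunity>  kind = %s, S_T = %s%s\n",
              attr(x, "kind"), format(attr(x, "S_T")),
              if (!is.na(attr(x, "theta"))) sprintf(", theta = %g", attr(x, "theta")) else ""))
  if (nrow(x)) NextMethod() else invisible(x)
}

meta_kind <- function(meta) attr(meta, "kind") %||% "logseries"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a metacommunity frequency table
#'
#' The format is two tab-separated columns, `species` and `rel_abundance`,
#' with comment lines starting `#`. The header comment records the pool kind
#' and parameters so the object round-trips.
#'
#' @param meta A [meta_logseries()]-style metacommunity.
#' @param path File path.
#' @return `read_metacommunity()` returns a `metacommunity` tibble;
#'   `write_metacommunity()` returns `path` invisibly.
#' @export
write_metacommunity <- function(meta, path) {
  hdr <- sprintf("# metacommunity kind=%s theta=%s S_T=%s",
                 attr(meta, "kind"), format(attr(meta, "theta")),
                 format(attr(meta, "S_T")))
  writeLines(c(hdr, "# species\trel_abundance",
               sprintf("%d\t%.17g", meta$species, meta$p)), path)
  invisible(path)
}

#' @rdname write_metacommunity
#' @export
read_metacommunity <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  hdr <- lines[grepl("^# metacommunity", lines)]
  kind <- "logseries"; theta <- NA_real_; S_T <- NA_real_
  if (length(hdr)) {
    gv <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr[1])
    kind <- gv("kind")
    theta <- suppressWarnings(as.numeric(gv("theta")))
    S_T <- suppressWarnings(as.numeric(gv("S_T")))
  }
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(dat)) {
    if (identical(kind, "infinite_even")) return(meta_infinite())
    abort(paste0("no data lines in ", path))
  }
  parts <- strsplit(trimws(dat), "\\s+")
  p <- as.numeric(vapply(parts, `[`, "", 2L))
  if (any(is.na(p)) || any(p <= 0)) abort("relative abundances must be positive numbers")
  out <- new_metacommunity(p / sum(p), kind = kind, theta = theta,
                           S_T = if (is.na(S_T)) length(p) else S_T)
  out$species <- as.integer(vapply(parts, `[`, "", 1L))
  out
}
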