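#' Summary statistics of three large tropical-forest censuses
#'
#' Community size, mean species richness, and mean Shannon index (averaged
#' over census years) for the Barro Colorado Island, Pasoh Forest Reserve
#' and Lambir Hills National Park 50-ha plots, as published. These are the
#' targets used when matching non-neutral model parameters to empirical
#' data with [fit_to_targets()].
#'
#' @return A tibble with columns `forest`, `J`, `S`, `shannon`.
#' @examples
#' forest_targets()
#' @export
forest_targets <- function() {
  path <- system.file("extdata", "forest_summary_stats.tsv", package = "sadpower")
  df <- utils::read.delim(path, comment.char = "#")
  tibble::as_tibble(df)
}

#' Deterministic fixture samples for testing and demonstrations
#'
#' Builds a small bundle of abundance samples with known properties: the
#' exhaustive-enumeration sizes (`J = 5` partitions), a monodominant
#' sample, a perfectly even sample, and a few neutral urn draws. The bundle
#' is a pure function of `seed`, so regenerating it reproduces identical
#' objects.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, every sample is also written
#'   as a two-column TSV (plus the forest summary table).
#' @return A named list of [abundance_sample()] objects (invisibly returns
#'   the directory when `dir` is given).
#' @export
make_fixtures <- function(seed = 1L, dir = NULL) {
  bundle <- with_local_seed(seed, {
    urns <- purrr::map(1:3, function(i) urn_sample(theta = 5, m = 0.5, J = 40))
    names(urns) <- paste0("urn_", 1:3)
    c(list(
      partitions_J5 = abundance_sample(c(2, 2, 1)),
      monodominant = abundance_sample(100),
      uniform = abundance_sample(rep(10, 100))
    ), urns)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    purrr::iwalk(bundle, function(d, nm) {
      write_abundance(d, file.path(dir, paste0(nm, ".tsv")), format = "tsv")
    })
    file.copy(system.file("extdata", "forest_summary_stats.tsv", package = "sadpower"),
              file.path(dir, "forest_summary_stats.tsv"), overwrite = TRUE)
    return(invisible(dir))
  }
  bundle
}
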