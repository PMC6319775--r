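#' Construct a metapopulation landscape
#'
#' A landscape describes the spatial substrate of the transmission model: a
#' set of sub-populations with relative sizes and pairwise distances.
#' Distances are supplied, never derived from coordinates internally, so
#' ecologically meaningful non-Euclidean metrics (e.g. shortest paths
#' through continuous habitat) can be used; optional coordinates are kept
#' only for plotting.
#'
#' @param sites A data frame with columns `id` (unique sub-population
#'   identifiers), `size_fraction` (positive, summing to 1: the proportion
#'   of the total population in each sub-population) and optionally `x`,
#'   `y` coordinates.
#' @param distances Square symmetric numeric matrix of positive pairwise
#'   distances (zero diagonal), rows/columns ordered as `sites$id`.
#'   Dimnames, if present, must match the ids.
#' @param total_population Optional positive total number of individuals
#'   `N`; required only for absolute-rate (per-day `alpha`/`m`) runs.
#' @return An object of class `landscape`: a list with elements `sites`
#'   (tibble), `distances` (matrix with id dimnames) and
#'   `total_population`.
#' @examples
#' two <- make_two_patch(0.5, distance = 1, seed_fraction = 0.01)
#' two$landscape
#' @export
landscape <- function(sites, distances, total_population = NULL) {
  sites <- tibble::as_tibble(sites)
  if (!all(c("id", "size_fraction") %in% names(sites))) {
    stop("`sites` needs columns `id` and `size_fraction`.", call. = FALSE)
  }
  sites$id <- as.character(sites$id)
  distances <- as.matrix(distances)
  dimnames(distances) <- list(sites$id, sites$id)
  obj <- structure(
    list(
      sites = sites,
      distances = distances,
      total_population = total_population
    ),
    class = "landscape"
  )
  validate_landscape(obj)
}

#' @export
print.landscape <- function(x, ...) {
  cat(
    "<landscape> ", nrow(x$sites), " sub-populations",
    if (!is.null(x$total_population)) {
      paste0(", N = ", format(x$total_population))
    },
    "\n",
    sep = ""
  )
  print(x$sites, n = 5)
  invisible(x)
}

validate_landscape <- function(x, tol = 1e-8) {
  sites <- x$sites
  d <- x$distances
  if (anyDuplicated(sites$id)) {
    stop("duplicated sub-population id: ",
         sites$id[duplicated(sites$id)][1], call. = FALSE)
  }
  if (any(sites$size_fraction <= 0)) {
    bad <- sites$id[sites$size_fraction <= 0][1]
    stop("size_fraction must be > 0 (sub-population ", bad, ").",
         call. = FALSE)
  }
  if (abs(sum(sites$size_fraction) - 1) > tol) {
    stop("size fractions must sum to 1 (got ",
         format(sum(sites$size_fraction)), ").", call. = FALSE)
  }
  J <- nrow(sites)
  if (!is.matrix(d) || nrow(d) != J || ncol(d) != J) {
    stop("distance matrix must be ", J, " x ", J, ".", call. = FALSE)
  }
  if (any(abs(diag(d)) > 0)) {
    stop("distance matrix diagonal must be zero.", call. = FALSE)
  }
  asym <- which(abs(d - t(d)) > tol, arr.ind = TRUE)
  if (nrow(asym) > 0) {
    i <- asym[1, 1]; j <- asym[1, 2]
    stop("distance matrix is asymmetric at (", sites$id[i], ", ",
         sites$id[j], "): ", d[i, j], " vs ", d[j, i], ".", call. = FALSE)
  }
  off <- d[upper.tri(d)]
  if (any(off <= 0)) {
    k <- which(upper.tri(d), arr.ind = TRUE)[which(off <= 0)[1], ]
    stop("off-diagonal distance must be > 0 at (", sites$id[k[1]], ", ",
         sites$id[k[2]], ").", call. = FALSE)
  }
  if (!is.null(x$total_population) &&
      (!is.numeric(x$total_population) || x$total_population <= 0)) {
    stop("`total_population` must be positive.", call. = FALSE)
  }
  x
}

n_patches <- function(landscape) nrow(landscape$sites)

#' Construct a seeding plan
#'
#' A seeding plan gives, for each sub-population, the initial fraction of
#' that sub-population made up of innovators using each solution; the
#' remainder starts naive.  Sub-populations absent from the plan start
#' fully naive.
#'
#' @param id Character vector of sub-population ids.
#' @param s1,s2 Initial innovator fractions (in \[0, 1\], `s1 + s2 <= 1`
#'   per sub-population) for solutions s1 and s2; recycled to the length
#'   of `id`.
#' @return A tibble with columns `id`, `s1`, `s2`.
#' @examples
#' seeding_plan(c("P1", "P2"), s1 = c(0.01, 0), s2 = c(0, 0.01))
#' @export
seeding_plan <- function(id, s1 = 0, s2 = 0) {
  plan <- tibble::tibble(id = as.character(id), s1 = s1, s2 = s2)
  if (any(plan$s1 < 0 | plan$s2 < 0 | plan$s1 + plan$s2 > 1)) {
    stop("seeding fractions must satisfy s1, s2 >= 0 and s1 + s2 <= 1.",
         call. = FALSE)
  }
  plan
}

#' Two sub-population landscape with opposed innovators
#'
#' The baseline setting: two sub-populations a fixed distance apart,
#' innovators of s1 seeded in the first and innovators of s2 in the
#' second, each as a fraction of the local population.
#'
#' @param size_fraction_1 Size fraction of sub-population P1, in (0, 1);
#'   P2 gets the complement.
#' @param distance Positive distance between the two (default 1; with two
#'   sub-populations changing it is equivalent to changing the movement
#'   rate).
#' @param seed_fraction Innovator fraction per seeded sub-population
#'   (default 0.01, i.e. 1% of the local population).
#' @param total_population Optional total `N` for absolute-rate runs.
#' @return A list with elements `landscape` and `seeding`.
#' @examples
#' make_two_patch(0.5)
#' @export
make_two_patch <- function(size_fraction_1, distance = 1,
                           seed_fraction = 0.01, total_population = NULL) {
  if (size_fraction_1 <= 0 || size_fraction_1 >= 1) {
    stop("`size_fraction_1` must lie in (0, 1).", call. = FALSE)
  }
  if (distance <= 0) stop("`distance` must be > 0.", call. = FALSE)
  if (seed_fraction < 0 || seed_fraction > 1) {
    stop("`seed_fraction` must lie in [0, 1].", call. = FALSE)
  }
  ls <- landscape(
    tibble::tibble(
      id = c("P1", "P2"),
      size_fraction = c(size_fraction_1, 1 - size_fraction_1)
    ),
    matrix(c(0, distance, distance, 0), 2, 2),
    total_population = total_population
  )
  list(
    landscape = ls,
    seeding = seeding_plan(c("P1", "P2"),
                           s1 = c(seed_fraction, 0),
                           s2 = c(0, seed_fraction))
  )
}

#' Three sub-population landscape with one naive sub-population
#'
#' P1 and P3 sit at distance 1 from each other; P2 sits at a common,
#' possibly larger, distance from both, emulating increasing habitat
#' fragmentation.  s1-innovators are seeded in P1, s2-innovators in P2,
#' and P3 starts fully naive.
#'
#' @param size_fractions Length-3 positive vector summing to 1
#'   (P1, P2, P3).
#' @param distance_P2 Distance from P2 to each of P1 and P3 (> 0).
#' @inheritParams make_two_patch
#' @return A list with elements `landscape` and `seeding`.
#' @examples
#' make_three_patch(rep(1 / 3, 3), distance_P2 = 5)
#' @export
make_three_patch <- function(size_fractions, distance_P2 = 1,
                             seed_fraction = 0.01, total_population = NULL) {
  if (length(size_fractions) != 3 || any(size_fractions <= 0) ||
      abs(sum(size_fractions) - 1) > 1e-8) {
    stop("`size_fractions` must be 3 positive values summing to 1.",
         call. = FALSE)
  }
  if (distance_P2 <= 0) stop("`distance_P2` must be > 0.", call. = FALSE)
  if (seed_fraction < 0 || seed_fraction > 1) {
    stop("`seed_fraction` must lie in [0, 1].", call. = FALSE)
  }
  d <- matrix(0, 3, 3)
  d[1, 3] <- d[3, 1] <- 1
  d[1, 2] <- d[2, 1] <- distance_P2
  d[2, 3] <- d[3, 2] <- distance_P2
  ls <- landscape(
    tibble::tibble(id = c("P1", "P2", "P3"), size_fraction = size_fractions),
    d,
    total_population = total_population
  )
  list(
    landscape = ls,
    seeding = seeding_plan(c("P1", "P2", "P3"),
                           s1 = c(seed_fraction, 0, 0),
                           s2 = c(0, seed_fraction, 0))
  )
}

#' Synthetic gridded landscape
#'
#' Generates a reproducible landscape of sub-populations on an
#' evenly-spaced rectangular grid with heterogeneous sizes, emulating a
#' woodland study site instrumented with a regular grid of feeding
#' stations (each feeder defining one sub-population).  Distances are
#' Euclidean between grid points, in units of the grid spacing.
#'
#' @param n_sites Number of sub-populations (>= 2); default 60.
#' @param size_distribution `"lognormal"` (heterogeneous sizes, sdlog 0.5)
#'   or `"uniform"` (equal sizes).
#' @param rng_seed Integer seed; the same seed always yields the same
#'   landscape, and the global RNG state is left untouched.
#' @param spacing Grid spacing in distance units (default 1).
#' @param total_population Optional total `N` for absolute-rate runs.
#' @return A `landscape` with ids `F01`, `F02`, ... and coordinates.
#' @examples
#' make_synthetic_grid(12, rng_seed = 1)
#' @export
make_synthetic_grid <- function(n_sites = 60,
                                size_distribution = c("lognormal", "uniform"),
                                rng_seed = 1, spacing = 1,
                                total_population = NULL) {
  if (n_sites < 2) stop("`n_sites` must be >= 2.", call. = FALSE)
  size_distribution <- match.arg(size_distribution)
  ncol_grid <- ceiling(sqrt(n_sites))
  pts <- expand.grid(
    x = seq_len(ncol_grid),
    y = seq_len(ceiling(n_sites / ncol_grid))
  )[seq_len(n_sites), ] * spacing
  sizes <- switch(size_distribution,
    lognormal = withr::with_seed(rng_seed, stats::rlnorm(n_sites, 0, 0.5)),
    uniform = rep(1, n_sites)
  )
  sites <- tibble::tibble(
    id = sprintf("F%02d", seq_len(n_sites)),
    size_fraction = sizes / sum(sizes),
    x = pts$x,
    y = pts$y
  )
  landscape(sites, as.matrix(stats::dist(pts)),
            total_population = total_population)
}

#' Read and write landscapes as delimited text
#'
#' A landscape is stored as two CSV files under a common prefix:
#' `<prefix>_sites.csv` (columns `id, size_fraction[, x, y]`, plus a
#' `total_population` column when set) and `<prefix>_distances.csv` (the
#' square distance matrix, columns headed by the ids in site order).
#' Reading validates the result and round-trips all fields.
#'
#' @param path File prefix (no extension).
#' @param landscape A `landscape` object.
#' @return `read_landscape()` returns a `landscape`; `write_landscape()`
#'   returns `path` invisibly.
#' @examples
#' p <- file.path(tempdir(), "demo")
#' write_landscape(make_two_patch(0.5)$landscape, p)
#' read_landscape(p)
#' @export
read_landscape <- function(path) {
  sites <- readr::read_csv(paste0(path, "_sites.csv"),
                           show_col_types = FALSE)
  d <- as.matrix(readr::read_csv(paste0(path, "_distances.csv"),
                                 show_col_types = FALSE))
  total_population <- NULL
  if ("total_population" %in% names(sites)) {
    total_population <- sites$total_population[1]
    if (is.na(total_population)) total_population <- NULL
    sites$total_population <- NULL
  }
  if (!identical(colnames(d), as.character(sites$id))) {
    stop("distance matrix header does not match site ids.", call. = FALSE)
  }
  landscape(sites, d, total_population = total_population)
}

#' @rdname read_landscape
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "landscape"))
  sites <- landscape$sites
  if (!is.null(landscape$total_population)) {
    sites$total_population <- landscape$total_population
  }
  readr::write_csv(sites, paste0(path, "_sites.csv"))
  d <- tibble::as_tibble(landscape$distances, .name_repair = "minimal")
  readr::write_csv(d, paste0(path, "_distances.csv"))
  invisible(path)
}

#' Sub-population centrality
#'
#' Centrality of a sub-population is the median distance between itself
#' and all other sub-populations; the smaller the value, the more central
#' the sub-population.  Medians over an even number of distances use the
#' usual midpoint convention.
#'
#' @param landscape A `landscape`.
#' @param id Sub-population ids (default: all).
#' @return A tibble with columns `id` and `centrality`.
#' @examples
#' centrality(make_three_patch(rep(1 / 3, 3), distance_P2 = 5)$landscape)
#' @export
centrality <- function(landscape, id = landscape$sites$id) {
  id <- as.character(id)
  missing <- setdiff(id, landscape$sites$id)
  if (length(missing) > 0) {
    stop("unknown sub-population id: ", missing[1], call. = FALSE)
  }
  vals <- vapply(id, function(j) {
    stats::median(landscape$distances[j, setdiff(colnames(landscape$distances), j)])
  }, numeric(1))
  tibble::tibble(id = id, centrality = unname(vals))
}

# Expand a seeding plan to per-patch (s1, s2) vectors in landscape order.
seeding_vectors <- function(landscape, seeding) {
  ids <- landscape$sites$id
  missing <- setdiff(seeding$id, ids)
  if (length(missing) > 0) {
    stop("seeding refers to unknown sub-population: ", missing[1],
         call. = FALSE)
  }
  s1 <- s2 <- stats::setNames(numeric(length(ids)), ids)
  s1[seeding$id] <- seeding$s1
  s2[seeding$id] <- seeding$s2
  list(s1 = unname(s1), s2 = unname(s2))
}
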