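# Functional trait space: Gower dissimilarity on mixed traits, principal
# coordinates, and descriptive guild classification.

#' Gower dissimilarity between species
#'
#' Numeric Gower dissimilarity over the columns a trait set selects:
#' for each pair of species the mean over traits of `|x_i - x_j| / range`,
#' with trait ranges taken from the supplied table. All traits here are
#' numeric (percent-use columns and body mass), so no categorical branch is
#' needed. Traits with zero range across species carry no information and
#' are excluded from the mean (classic Gower weighting); they are flagged
#' in the `"zero_range"` attribute with a warning.
#'
#' @param traits Trait tibble with a `species` column and the canonical
#'   trait columns (see [trait_columns()]).
#' @param set Trait set: `"diet"`, `"strata"` or `"comb"`.
#' @param log_mass If `TRUE`, body mass enters on the log10 scale before
#'   range normalization (only relevant for `set = "comb"`).
#' @return A symmetric `n_species` x `n_species` matrix with zero diagonal
#'   and entries in \[0, 1\]; species ids as dimnames.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   species = c("a", "b", "c"),
#'   diet_inv = c(100, 50, 0), diet_vend = c(0, 50, 100),
#'   diet_vect = 0, diet_vfish = 0, diet_vunk = 0, diet_scav = 0,
#'   diet_fruit = 0, diet_nect = 0, diet_seed = 0
#' )
#' gower_dissimilarity(tr, "diet")["a", "c"]
gower_dissimilarity <- function(traits, set = c("diet", "strata", "comb"),
                                log_mass = FALSE) {
  set <- match.arg(set)
  cols <- trait_columns(set)
  assert_columns(traits, c("species", cols), "trait table")
  if (nrow(traits) < 2) abort("Gower dissimilarity needs at least 2 species")

  x <- as.matrix(traits[cols])
  storage.mode(x) <- "double"
  if (log_mass && "body_mass" %in% cols) {
    x[, "body_mass"] <- log10(x[, "body_mass"])
  }
  rng <- apply(x, 2, function(col) diff(range(col)))
  zero_range <- cols[rng == 0]
  if (length(zero_range) == length(cols)) {
    abort("all selected traits are constant across species")
  }
  if (length(zero_range) > 0) {
    warn(paste0("trait(s) with zero range contribute 0 to Gower: ",
                paste(zero_range, collapse = ", ")))
  }
  keep <- rng > 0
  xs <- sweep(x[, keep, drop = FALSE], 2, rng[keep], "/")
  n <- nrow(xs)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(xs))) {
    d <- d + abs(outer(xs[, j], xs[, j], "-"))
  }
  d <- d / sum(keep)  # zero-range traits are excluded, as in classic Gower
  dimnames(d) <- list(traits$species, traits$species)
  attr(d, "zero_range") <- zero_range
  d
}

#' Principal coordinates of a dissimilarity matrix
#'
#' Classical metric scaling (double-centred eigendecomposition, via
#' [stats::cmdscale()]) of a species dissimilarity matrix. All axes with a
#' positive eigenvalue are retained, so Euclidean distances among the
#' coordinates reproduce the input exactly whenever it is
#' Euclidean-embeddable; no truncation is applied because the downstream
#' dispersion index is distance-based and truncation would change it.
#'
#' For non-Euclidean input, `correction = "sqrt"` takes the element-wise
#' square root of the dissimilarities and `correction = "cailliez"` adds
#' the Cailliez constant; with `correction = "none"` a warning is issued
#' when the negative eigenvalues exceed 5% of the total absolute
#' eigenvalue mass.
#'
#' @param d Symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param correction `"none"` (default), `"sqrt"`, or `"cailliez"`.
#' @param tol Eigenvalues below `tol * max(eigenvalue)` are dropped.
#' @return An object of class `"trait_space"`: list with `coordinates`
#'   (species x axes), `eigenvalues` (all, descending), `correction`, and
#'   `negative_fraction` (share of absolute eigenvalue mass that was
#'   negative before retention).
#' @export
trait_pcoa <- function(d, correction = c("none", "sqrt", "cailliez"),
                       tol = 1e-8) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    abort("dissimilarity matrix must be symmetric")
  }
  if (any(d < 0)) abort("dissimilarities must be non-negative")
  n <- nrow(d)
  du <- if (correction == "sqrt") sqrt(d) else d
  fit <- suppressWarnings(
    stats::cmdscale(du, k = n - 1, eig = TRUE,
                    add = correction == "cailliez")
  )
  eig <- fit$eig
  neg_mass <- sum(abs(eig[eig < 0])) / sum(abs(eig))
  if (correction == "none" && neg_mass > 0.05) {
    warn(sprintf(paste0("negative eigenvalues carry %.1f%% of absolute ",
                        "eigenvalue mass; consider a correction"),
                 100 * neg_mass))
  }
  keep <- which(eig > tol * max(eig))
  coords <- fit$points[, keep, drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("axis_", seq_along(keep))
  structure(
    list(coordinates = coords, eigenvalues = eig, correction = correction,
         negative_fraction = neg_mass),
    class = "trait_space"
  )
}

#' @export
print.trait_space <- function(x, ...) {
  cat("<trait_space> ", nrow(x$coordinates), " species x ",
      ncol(x$coordinates), " axes (correction: ", x$correction, "; ",
      sprintf("%.1f%%", 100 * x$negative_fraction),
      " negative eigenvalue mass)\n", sep = "")
  invisible(x)
}

#' Build the trait space for a trait set
#'
#' Convenience wrapper: Gower dissimilarity on the trait set's columns
#' followed by principal coordinates. The space is built once from the full
#' species pool so that site-level dispersion values are comparable across
#' sites.
#'
#' @inheritParams gower_dissimilarity
#' @inheritParams trait_pcoa
#' @return A `"trait_space"` object (see [trait_pcoa()]).
#' @export
build_trait_space <- function(traits, set = c("diet", "strata", "comb"),
                              correction = "none", log_mass = FALSE,
                              tol = 1e-8) {
  trait_pcoa(gower_dissimilarity(traits, set, log_mass = log_mass),
             correction = correction, tol = tol)
}

# diet categories collapsed for guild assignment; "unknown" is excluded
DIET_COLLAPSE <- list(
  invertebrate = "diet_inv",
  plant_seed = c("diet_fruit", "diet_nect", "diet_seed"),
  vertebrate = c("diet_vend", "diet_vect", "diet_vfish", "diet_scav")
)
STRATUM_GROUPS <- c(ground = "strat_ground", understory = "strat_understory",
                    midhigh = "strat_midhigh", canopy = "strat_canopy")

#' Descriptive guild classification
#'
#' Assigns each species a main diet and a main foraging stratum. Diet
#' percentages are collapsed to three groups — invertebrate,
#' plant/seed (fruit + nectar + seed) and vertebrate (mammals & birds +
#' reptiles & amphibians + fish + scavenged), with "unknown" excluded —
#' and a species whose largest group stays below `omnivore_threshold`
#' percent is classed omnivore. The main stratum is the argmax over ground,
#' understory, mid-high and canopy (aquatic and aerial strata excluded).
#' Ties are broken by the fixed order of the groups above and flagged.
#'
#' @param traits Trait tibble with the canonical columns.
#' @param omnivore_threshold Percent a collapsed diet group must reach for
#'   the species not to be classed omnivore (default 50).
#' @return Tibble: `species`, `main_diet`, `diet_tie`, `main_stratum`,
#'   `stratum_tie`.
#' @export
derive_guilds <- function(traits, omnivore_threshold = 50) {
  assert_columns(traits, c("species", DIET_COLS, STRATA_COLS), "trait table")
  diet_grp <- vapply(DIET_COLLAPSE,
                     function(cc) rowSums(traits[, cc, drop = FALSE]),
                     numeric(nrow(traits)))
  if (nrow(traits) == 1) diet_grp <- matrix(diet_grp, nrow = 1,
                                            dimnames = list(NULL,
                                              names(DIET_COLLAPSE)))
  argmax_fixed <- function(m) {
    best <- apply(m, 1, max)
    idx <- apply(m, 1, which.max)  # first max = fixed category order
    tie <- apply(m, 1, function(r) sum(r == max(r)) > 1)
    list(label = colnames(m)[idx], best = best, tie = tie)
  }
  dm <- argmax_fixed(diet_grp)
  main_diet <- ifelse(dm$best < omnivore_threshold, "omnivore", dm$label)
  diet_tie <- dm$tie & dm$best >= omnivore_threshold

  strata <- as.matrix(traits[, unname(STRATUM_GROUPS)])
  colnames(strata) <- names(STRATUM_GROUPS)
  sm <- argmax_fixed(strata)

  tibble::tibble(
    species = traits$species,
    main_diet = main_diet, diet_tie = diet_tie,
    main_stratum = sm$label, stratum_tie = sm$tie
  )
}
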