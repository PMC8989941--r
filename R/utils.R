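# Internal helpers shared across modules.

DIET_COLS <- c("diet_inv", "diet_vend", "diet_vect", "diet_vfish",
               "diet_vunk", "diet_scav", "diet_fruit", "diet_nect",
               "diet_seed")

STRATA_COLS <- c("strat_watbelowsurf", "strat_wataroundsurf", "strat_ground",
                 "strat_understory", "strat_midhigh", "strat_canopy",
                 "strat_aerial")

COMPONENT_NAMES <- c("rich_l", "comp_l", "rich_g", "comp_g", "abun")

# EltonTraits 1.0 column dialect -> canonical names.
ELTON_MAP <- c(
  "Diet-Inv" = "diet_inv", "Diet-Vend" = "diet_vend",
  "Diet-Vect" = "diet_vect", "Diet-Vfish" = "diet_vfish",
  "Diet-Vunk" = "diet_vunk", "Diet-Scav" = "diet_scav",
  "Diet-Fruit" = "diet_fruit", "Diet-Nect" = "diet_nect",
  "Diet-Seed" = "diet_seed",
  "ForStrat-watbelowsurf" = "strat_watbelowsurf",
  "ForStrat-wataroundsurf" = "strat_wataroundsurf",
  "ForStrat-ground" = "strat_ground",
  "ForStrat-understory" = "strat_understory",
  "ForStrat-midhigh" = "strat_midhigh",
  "ForStrat-canopy" = "strat_canopy",
  "ForStrat-aerial" = "strat_aerial",
  "BodyMass-Value" = "body_mass"
)

#' Trait columns used by a trait set
#'
#' Maps a trait-set name to the canonical trait-table columns it selects:
#' `"diet"` selects the nine diet percent-use columns, `"strata"` the seven
#' foraging-stratum percent-use columns, and `"comb"` their union plus body
#' mass.
#'
#' @param set One of `"diet"`, `"strata"`, `"comb"`.
#' @return Character vector of column names.
#' @export
#' @examples
#' trait_columns("diet")
trait_columns <- function(set = c("diet", "strata", "comb")) {
  set <- match.arg(set)
  switch(set,
    diet = DIET_COLS,
    strata = STRATA_COLS,
    comb = c(DIET_COLS, STRATA_COLS, "body_mass")
  )
}

# One master seed spawns a fixed substream per named operation, so adding
# draws in one generator never shifts another's stream.
op_seed <- function(seed, op) {
  offsets <- c(traits = 101, counts = 211, environment = 307, pairs = 401,
               pipeline = 503)
  if (!op %in% names(offsets)) {
    abort(paste0("unknown operation for seed substream: ", op))
  }
  ((as.numeric(seed) %% 1000003) * 2017 + offsets[[op]] * 10007) %% 2147483647
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
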