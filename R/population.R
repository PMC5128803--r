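## Synthetic population distributions and drug profiles.
##
## Circulating/intracellular spermine varies almost five-fold between
## individuals (diet, age, metabolic state); the default population model
## is normal(3, 0.75) uM clipped at zero, so the five-fold spread spans
## roughly mean +/- 2 SD and mean + 3 SD marks the 0.2% tail individual.
## A right-skewed lognormal alternative with the same mean and SD is
## provided.

#' Population distribution of a model parameter
#'
#' @param name model parameter name (e.g. `"spm"`, `"g_CaL"`).
#' @param mean,sd distribution mean and standard deviation (sd >= 0).
#' @param distribution `"normal"` or `"lognormal"` (moment-matched).
#' @param floor lower clip bound (>= 0).
#' @return Object of class `torsim_popspec`.
#' @export
population_spec <- function(name, mean, sd, distribution = c("normal",
                                                             "lognormal"),
                            floor = 0) {
  distribution <- match.arg(distribution)
  if (!is.numeric(sd) || is.na(sd) || sd < 0) {
    stop("sd must be >= 0", call. = FALSE)
  }
  if (!is.numeric(floor) || floor < 0) stop("floor must be >= 0",
                                            call. = FALSE)
  if (distribution == "lognormal" && mean <= 0) {
    stop("lognormal requires mean > 0", call. = FALSE)
  }
  structure(list(name = as.character(name), mean = mean, sd = sd,
                 distribution = distribution, floor = floor),
            class = "torsim_popspec")
}

#' Default spermine population spec: normal(3, 0.75) uM, clipped at 0
#' @export
spm_population_spec <- function() population_spec("spm", 3, 0.75)

.as_spec_list <- function(specs) {
  if (inherits(specs, "torsim_popspec")) return(list(specs))
  if (is.data.frame(specs)) {
    return(lapply(seq_len(nrow(specs)), function(i) {
      population_spec(specs$name[i], specs$mean[i], specs$sd[i],
                      floor = if ("floor" %in% names(specs))
                        specs$floor[i] else 0)
    }))
  }
  stopifnot(is.list(specs),
            all(vapply(specs, inherits, TRUE, "torsim_popspec")))
  specs
}

#' Sample a population parameter (e.g. intracellular spermine)
#'
#' Reproducible draws from the spec's distribution, clipped at its floor.
#'
#' @param n number of individuals (>= 1).
#' @param spec a [population_spec()]; default the spermine spec.
#' @param seed integer seed (local to this call; the global RNG state is
#'   untouched).
#' @return Numeric vector of length `n`.
#' @export
sample_spm <- function(n, spec = spm_population_spec(), seed = 1) {
  stopifnot(inherits(spec, "torsim_popspec"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  x <- .with_local_seed(seed, {
    if (spec$distribution == "normal") {
      stats::rnorm(n, spec$mean, spec$sd)
    } else {
      ## moment-matched lognormal
      s2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(n, meanlog = log(spec$mean) - s2 / 2, sdlog = sqrt(s2))
    }
  })
  pmax(x, spec$floor)
}

.with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mean and extreme (+/- 3 SD) levels of a population spec
#'
#' The three levels used in the `3^n` extreme-value scan; each extreme
#' represents 0.2% of the population (above or under mean +/- 3 SD). The
#' low level is clipped at the spec's floor (attribute `clipped`).
#'
#' @param spec a [population_spec()].
#' @return Numeric `c(low, mean, high)`.
#' @export
extreme_levels <- function(spec) {
  stopifnot(inherits(spec, "torsim_popspec"))
  lo <- spec$mean - 3 * spec$sd
  clipped <- lo < spec$floor
  structure(c(low = max(lo, spec$floor), mean = spec$mean,
              high = spec$mean + 3 * spec$sd),
            clipped = clipped)
}

#' Synthesize a drug profile typical of a torsadogenic-risk group
#'
#' Generates a random profile whose pD2 pattern lands on the decision-tree
#' branch characteristic of the group: A1 — weak (pD2 < 6) pure I_Kr
#' blocker; A2 — potent I_Kr block plus other-current (I_Na/I_Ks/I_K1)
#' involvement; B — potent I_Kr block with weaker I_CaL block; C — I_CaL
#' block more potent than I_Kr block.
#'
#' @param group `"A1"`, `"A2"`, `"B"` or `"C"`.
#' @param seed integer seed.
#' @return A [drug_profile()] with `known_group` set.
#' @export
make_synthetic_drug <- function(group = c("A1", "A2", "B", "C"), seed = 1) {
  group <- match.arg(group)
  .with_local_seed(seed, {
    r <- function(lo, hi) stats::runif(1, lo, hi)
    prof <- switch(group,
      A1 = list(kr = 10^-r(4, 5.9)),
      A2 = list(kr = 10^-r(6, 8), na = 10^-r(4.5, 6),
                ik1 = r(10, 40)),
      B = list(kr = 10^-r(6, 8), cal = NA),
      C = list(kr = 10^-r(6, 7.5))
    )
    if (group == "B") {
      kr_pd2 <- pd2(prof$kr)
      prof$cal <- 10^-r(4, kr_pd2 - 0.2) # CaL strictly less potent
    }
    if (group == "C") {
      kr_pd2 <- pd2(prof$kr)
      prof$cal <- 10^-r(kr_pd2 + 0.2, kr_pd2 + 2) # CaL more potent
    }
    drug_profile(
      name = sprintf("synthetic_%s_%d", group, seed),
      ic50_na = if (!is.null(prof$na)) prof$na else NA,
      ic50_cal = if (!is.null(prof$cal)) prof$cal else NA,
      ic50_kr = prof$kr,
      ik1_block_pct = if (!is.null(prof$ik1)) prof$ik1 else 0,
      concentration = prof$kr, # test at the I_Kr IC50
      known_group = group
    )
  })
}

#' The 11-compound reference library
#'
#' The classic multichannel QT-prolongation panel with its clinical
#' torsadogenic-risk group labels: A1 dofetilide, sotalol; A2 terfenadine,
#' thioridazine, quinidine; B moxifloxacin, verapamil, risperidone;
#' C phenytoin, propranolol, nicardipine. IC50s and test concentrations are
#' literature-derived plausible configuration values (see the `provenance`
#' column of the shipped table), not measurements made by this package.
#'
#' @return Named list of 11 [drug_profile()] objects.
#' @export
default_drug_library <- function() {
  path <- system.file("extdata", "drug_library.csv", package = "torsim",
                      mustWork = TRUE)
  lib <- read_drug_table(path)
  if (length(lib) != 11) stop("shipped drug library is malformed",
                              call. = FALSE)
  lib
}
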