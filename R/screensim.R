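# Stochastic simulator of the pooled PCR deletion screen: a mutagenized worm
# library arrayed in 96-well plates, DNA pooled by row and column, nested PCR
# on pools, addressing of positive row x column intersections, then rounds of
# sib selection (regrow, sample, PCR) at decreasing seed density until a
# single-parent population segregating the deletion is found, or - for
# recessive lethal alleles - a persistent heterozygote is stabilized.
#
# PCR detection model: one reaction samples an aliquot of pooled DNA; given
# the pool contains at least one carrier, the number of mutant templates in
# the aliquot is zero-truncated Poisson with mean (pool mutant fraction x
# templates_per_reaction), and each template is detected independently with
# probability s, so P(positive) = E[1 - (1-s)^m]. Mutant-free pools never
# fire (nested PCR is modeled as fully specific). Duplicate screening runs
# two independent reactions and calls the pool positive if either fires.

#' Define a screening scenario
#'
#' Bundles the library, plate, PCR, and sib-selection parameters for one
#' simulated screen of a single deletion target.
#'
#' @param plates number of 96-well plates in the library.
#' @param plate_rows,plate_cols plate geometry (8 x 12 by default).
#' @param genomes_per_well mutagenized genomes represented in one well's
#'   population.
#' @param deletion_rate_per_target probability that one mutagenized genome
#'   carries a deletion at the screened target (typical screens recover a hit
#'   from libraries of 1e5-1e6 genomes, i.e. rates of order 1e-6 to 1e-5).
#' @param pcr_sensitivity per-template detection probability `s` in `(0, 1]`.
#' @param duplicate_screening run each pool reaction in duplicate and call
#'   positive on either firing.
#' @param templates_per_reaction expected genome templates sampled into one
#'   PCR aliquot.
#' @param sib_plan integer vector: number of sub-populations tested in each
#'   sib-selection round.
#' @param sib_seed_worms integer vector parallel to `sib_plan`: worms seeded
#'   per sub-population per round; must be non-increasing and end at 1
#'   (single-parent picks), mirroring the tens-to-singles enrichment. The
#'   default four-round schedule (50, 10, 1, 1 worms across 24
#'   sub-populations each) reliably concentrates a 1-in-500 carrier well to
#'   single-parent deletion populations.
#' @param brood_factor population growth per selfing generation.
#' @param lethal is the target a recessive lethal (homozygotes arrest before
#'   reproducing)?
#' @param mutagenized_genomes_total genomes represented by the whole library;
#'   libraries between 125,000 and 1.4 million genomes are flagged
#'   `paper_scale` in the printout.
#' @return an object of class `"screen_scenario"`.
#' @export
screen_scenario <- function(plates = 10L, plate_rows = 8L, plate_cols = 12L,
                            genomes_per_well = 500L,
                            deletion_rate_per_target = 5e-6,
                            pcr_sensitivity = 0.95,
                            duplicate_screening = TRUE,
                            templates_per_reaction = 10000,
                            sib_plan = c(24L, 24L, 24L, 24L),
                            sib_seed_worms = c(50L, 10L, 1L, 1L),
                            brood_factor = 100L,
                            lethal = FALSE,
                            mutagenized_genomes_total =
                              plates * plate_rows * plate_cols *
                              genomes_per_well) {
  if (plates < 0 || plate_rows < 1 || plate_cols < 1) {
    ds_stop("need plates >= 0 and positive plate geometry",
            "delscreen_config_error")
  }
  if (genomes_per_well < 1) {
    ds_stop("genomes_per_well must be >= 1", "delscreen_config_error")
  }
  if (deletion_rate_per_target < 0 || deletion_rate_per_target > 1) {
    ds_stop("deletion_rate_per_target must be a probability",
            "delscreen_config_error")
  }
  if (pcr_sensitivity <= 0 || pcr_sensitivity > 1) {
    ds_stop("pcr_sensitivity must be in (0, 1]", "delscreen_config_error")
  }
  if (length(sib_plan) < 1L || any(sib_plan < 1L)) {
    ds_stop("sib_plan must give >= 1 sub-population per round",
            "delscreen_config_error")
  }
  if (length(sib_seed_worms) != length(sib_plan)) {
    ds_stop("sib_seed_worms must parallel sib_plan", "delscreen_config_error")
  }
  if (any(diff(sib_seed_worms) > 0) ||
      sib_seed_worms[length(sib_seed_worms)] != 1L) {
    ds_stop("sib_seed_worms must be non-increasing and end at 1",
            "delscreen_config_error")
  }
  structure(
    list(plates = as.integer(plates), plate_rows = as.integer(plate_rows),
         plate_cols = as.integer(plate_cols),
         n_wells = as.integer(plates * plate_rows * plate_cols),
         genomes_per_well = as.integer(genomes_per_well),
         deletion_rate_per_target = deletion_rate_per_target,
         pcr_sensitivity = pcr_sensitivity,
         duplicate_screening = isTRUE(duplicate_screening),
         templates_per_reaction = templates_per_reaction,
         sib_plan = as.integer(sib_plan),
         sib_seed_worms = as.integer(sib_seed_worms),
         brood_factor = as.integer(brood_factor),
         lethal = isTRUE(lethal),
         mutagenized_genomes_total = mutagenized_genomes_total),
    class = "screen_scenario"
  )
}

#' @export
print.screen_scenario <- function(x, ...) {
  scale_note <- if (x$mutagenized_genomes_total >= 125000 &&
                    x$mutagenized_genomes_total <= 1400000)
    " [paper_scale]" else ""
  cat(sprintf(
    "<screen_scenario> %d plate(s) x %dx%d = %d wells, %d genomes/well (%s genomes total%s)\n",
    x$plates, x$plate_rows, x$plate_cols, x$n_wells, x$genomes_per_well,
    format(x$mutagenized_genomes_total, big.mark = ","), scale_note))
  cat(sprintf(
    "  rate %.2g/genome, s = %.2f, duplicate = %s, lethal = %s, sib plan %s x %s worms\n",
    x$deletion_rate_per_target, x$pcr_sensitivity, x$duplicate_screening,
    x$lethal, paste(x$sib_plan, collapse = "/"),
    paste(x$sib_seed_worms, collapse = "/")))
  invisible(x)
}

#' Build a mutagenized worm library
#'
#' Each well holds `genomes_per_well` mutagenized genomes, each independently
#' carrying the target deletion with `deletion_rate_per_target`; carriers are
#' heterozygous F1 animals.
#'
#' @param sc a [screen_scenario()].
#' @return a `"screen_library"`: data.frame with one row per well
#'   (`well_id`, `plate`, `row`, `col`, `genomes`, `mutants`).
#' @export
build_library <- function(sc) {
  stopifnot(inherits(sc, "screen_scenario"))
  if (sc$n_wells == 0L) {
    lib <- data.frame(well_id = character(), plate = integer(),
                      row = integer(), col = integer(),
                      genomes = integer(), mutants = integer())
    class(lib) <- c("screen_library", "data.frame")
    return(lib)
  }
  grid <- expand.grid(row = seq_len(sc$plate_rows),
                      col = seq_len(sc$plate_cols),
                      plate = seq_len(sc$plates))
  lib <- data.frame(
    well_id = sprintf("P%02d-%s%02d", grid$plate,
                      LETTERS[grid$row], grid$col),
    plate = grid$plate, row = grid$row, col = grid$col,
    genomes = sc$genomes_per_well,
    mutants = rbinom(nrow(grid), sc$genomes_per_well,
                     sc$deletion_rate_per_target)
  )
  class(lib) <- c("screen_library", "data.frame")
  lib
}

#' Pool library DNA into per-plate row and column pools
#'
#' Every well contributes to exactly one row pool and one column pool of its
#' plate, so a single mutant well lights up one row and one column whose
#' intersection addresses it.
#'
#' @param lib a `"screen_library"` from [build_library()].
#' @return a `"pool_grid"`: data.frame with one row per pool (`plate`,
#'   `axis` = "row"/"col", `index`, `n_wells`, `mutants`, `genomes`,
#'   `fraction` = mutant template fraction).
#' @export
pool_dna <- function(lib) {
  stopifnot(inherits(lib, "screen_library"))
  pool_one <- function(axis) {
    key <- interaction(lib$plate, lib[[axis]], drop = TRUE)
    agg <- aggregate(cbind(mutants, genomes) ~ plate + idx,
                     data = data.frame(plate = lib$plate,
                                       idx = lib[[axis]],
                                       mutants = lib$mutants,
                                       genomes = lib$genomes),
                     FUN = sum)
    data.frame(plate = agg$plate, axis = axis, index = agg$idx,
               n_wells = as.integer(table(key)[paste(agg$plate, agg$idx,
                                                     sep = ".")]),
               mutants = agg$mutants, genomes = agg$genomes,
               fraction = agg$mutants / agg$genomes)
  }
  grid <- if (nrow(lib) == 0L) {
    data.frame(plate = integer(), axis = character(), index = integer(),
               n_wells = integer(), mutants = integer(), genomes = integer(),
               fraction = numeric())
  } else {
    rbind(pool_one("row"), pool_one("col"))
  }
  grid <- grid[order(grid$plate, grid$axis, grid$index), , drop = FALSE]
  rownames(grid) <- NULL
  class(grid) <- c("pool_grid", "data.frame")
  grid
}

#' One nested-PCR reaction on a DNA sample
#'
#' @param n_templates mutant template count in the aliquot.
#' @param s per-template detection probability.
#' @return logical: does the deletion band appear?
#' @export
pcr_reaction <- function(n_templates, s) {
  if (n_templates <= 0) return(FALSE)
  runif(1L) < 1 - (1 - s)^n_templates
}

#' Test one DNA sample under the scenario's PCR model
#'
#' Draws the aliquot template count (zero-truncated Poisson around
#' `fraction * templates_per_reaction` when carriers are present) and runs
#' one reaction, or two independent ones under duplicate screening (positive
#' if either fires).
#'
#' @param fraction mutant template fraction of the sample.
#' @param sc a [screen_scenario()].
#' @param duplicate override the scenario's duplicate setting (addressing
#'   and sib reactions are run singly).
#' @return list `positive` (logical) and `reactions` (count used).
#' @export
test_sample <- function(fraction, sc, duplicate = sc$duplicate_screening) {
  n_rxn <- if (duplicate) 2L else 1L
  if (fraction <= 0) {
    return(list(positive = FALSE, reactions = n_rxn))
  }
  lambda <- fraction * sc$templates_per_reaction
  pos <- FALSE
  for (i in seq_len(n_rxn)) {
    m <- rztpois(1L, lambda)
    if (pcr_reaction(m, sc$pcr_sensitivity)) pos <- TRUE
  }
  list(positive = pos, reactions = n_rxn)
}

#' Screen all pools by nested PCR
#'
#' @param grid a `"pool_grid"` from [pool_dna()].
#' @param sc a [screen_scenario()].
#' @return the grid with a logical `positive` column; attribute
#'   `"reactions"` records the reactions used.
#' @export
screen_pools <- function(grid, sc) {
  stopifnot(inherits(grid, "pool_grid"), inherits(sc, "screen_scenario"))
  reactions <- 0L
  pos <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    t <- test_sample(grid$fraction[i], sc)
    pos[i] <- t$positive
    reactions <- reactions + t$reactions
  }
  grid$positive <- pos
  attr(grid, "reactions") <- reactions
  grid
}

#' Address positive pools to individual library wells
#'
#' Per plate, candidate wells are the intersections of positive rows with
#' positive columns; each candidate is retested individually (single
#' reaction). A plate where pools fired but no candidate well confirmed - or
#' where a row fired with no matching column - is flagged lost at
#' addressing.
#'
#' @param screened a screened `"pool_grid"` (with `positive` column).
#' @param lib the `"screen_library"` the pools came from.
#' @param sc a [screen_scenario()].
#' @return list with `confirmed` (data.frame of confirmed wells),
#'   `candidates` (count tested), `reactions`, and `lost_at_addressing`
#'   (logical).
#' @export
address_positive <- function(screened, lib, sc) {
  stopifnot(inherits(screened, "pool_grid"))
  reactions <- 0L
  confirmed <- list()
  n_cand <- 0L
  lost <- FALSE
  for (p in unique(screened$plate[screened$positive])) {
    rows <- screened$index[screened$plate == p & screened$axis == "row" &
                           screened$positive]
    cols <- screened$index[screened$plate == p & screened$axis == "col" &
                           screened$positive]
    if (length(rows) == 0L || length(cols) == 0L) {
      lost <- TRUE  # a pool fired on one axis only: intersection is empty
      next
    }
    cand <- lib[lib$plate == p & lib$row %in% rows & lib$col %in% cols, ,
                drop = FALSE]
    n_cand <- n_cand + nrow(cand)
    hit <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      t <- test_sample(cand$mutants[i] / cand$genomes[i], sc,
                       duplicate = FALSE)
      hit[i] <- t$positive
      reactions <- reactions + t$reactions
    }
    if (!any(hit)) lost <- TRUE else confirmed[[length(confirmed) + 1L]] <-
        cand[hit, , drop = FALSE]
  }
  confirmed <- if (length(confirmed)) do.call(rbind, confirmed) else
    lib[0L, , drop = FALSE]
  list(confirmed = confirmed, candidates = n_cand,
       reactions = reactions, lost_at_addressing = lost)
}

#' One generation of selfing
#'
#' Offspring of a hermaphrodite population segregate 1 wild-type : 2
#' heterozygous : 1 homozygous-deletion per heterozygous parent; homozygous
#' parents breed true. For recessive lethal targets, homozygous animals
#' arrest before reproducing: they neither parent the next generation nor
#' appear among its surviving adults.
#'
#' @param counts named integer vector `c(wt=, het=, hom=)` of adults.
#' @param brood_factor offspring per adult.
#' @param lethal recessive lethal target?
#' @param max_pop cap on the adult population drawn (the culture saturates;
#'   genotype fractions are preserved by multinomial sampling).
#' @return named integer vector of surviving adult counts.
#' @export
self_generation <- function(counts, brood_factor, lethal = FALSE,
                            max_pop = 1e6) {
  counts <- counts[c("wt", "het", "hom")]
  if (lethal) counts["hom"] <- 0L
  n <- sum(counts)
  if (n == 0L) return(c(wt = 0L, het = 0L, hom = 0L))
  probs <- c(wt = counts[["wt"]] + counts[["het"]] / 4,
             het = counts[["het"]] / 2,
             hom = counts[["het"]] / 4 + counts[["hom"]]) / n
  n_off <- min(n * as.numeric(brood_factor), max_pop)
  off <- as.integer(rmultinom(1L, n_off, probs))
  names(off) <- c("wt", "het", "hom")
  if (lethal) off["hom"] <- 0L
  off
}

# Multivariate hypergeometric: draw k animals without replacement.
draw_worms <- function(counts, k) {
  pool <- rep(c("wt", "het", "hom"), times = counts[c("wt", "het", "hom")])
  picked <- sample(pool, k)
  c(wt = sum(picked == "wt"), het = sum(picked == "het"),
    hom = sum(picked == "hom"))
}

#' Run sib selection from a confirmed library well
#'
#' Each round regrows the current parent population by selfing, seeds
#' `sib_plan[r]` sub-populations of `sib_seed_worms[r]` animals each
#' (hypergeometric draws of carriers), expands and PCR-tests every
#' sub-population, and recurses into a positive one (preferring the highest
#' homozygote fraction, then the highest carrier frequency - the strongest
#' gel). Terminates `homozygous` when the chosen population derives from a
#' single homozygous parent (100% deletion segregation), `lost` when a round
#' yields no positive sub-population, and `persistent_heterozygous` when the
#' rounds are exhausted with carrier-positive but mixed populations - for
#' recessive lethals this is the expected end point, handed on to balancing.
#'
#' @param well one row of a `"screen_library"` (a confirmed well).
#' @param sc a [screen_scenario()].
#' @return a `"screen_result"`: list with `recovered` one of
#'   `"homozygous"`, `"persistent_heterozygous"`, `"lost"`; `rounds`, a
#'   per-round trace data.frame (`round`, `wells_tested`, `positives`,
#'   `allele_frequency`); and `reactions_used`.
#' @export
run_sib_selection <- function(well, sc) {
  stopifnot(inherits(sc, "screen_scenario"))
  if (nrow(well) != 1L || well$mutants < 1L) {
    ds_stop("sib selection needs one well containing >= 1 carrier",
            "delscreen_config_error")
  }
  pop <- c(wt = well$genomes - well$mutants, het = well$mutants, hom = 0L)
  trace <- data.frame(round = integer(), wells_tested = integer(),
                      positives = integer(), allele_frequency = numeric())
  reactions <- 0L
  recovered <- NA_character_
  for (r in seq_along(sc$sib_plan)) {
    parents <- self_generation(pop, sc$brood_factor, sc$lethal)
    n_sub <- sc$sib_plan[r]
    k <- sc$sib_seed_worms[r]
    if (sum(parents) < n_sub * k) {
      # tiny parent population: seed as many sub-populations as possible
      n_sub <- max(1L, sum(parents) %/% max(k, 1L))
    }
    subpops <- vector("list", n_sub)
    avail <- parents
    for (i in seq_len(n_sub)) {
      seed <- draw_worms(avail, min(k, sum(avail)))
      avail <- avail - seed
      subpops[[i]] <- self_generation(seed, sc$brood_factor, sc$lethal)
    }
    pos <- logical(n_sub)
    for (i in seq_len(n_sub)) {
      tot <- sum(subpops[[i]])
      frac <- if (tot == 0L) 0 else
        (subpops[[i]][["het"]] + subpops[[i]][["hom"]]) / tot
      t <- test_sample(frac, sc, duplicate = FALSE)
      pos[i] <- t$positive
      reactions <- reactions + t$reactions
    }
    if (!any(pos)) {
      trace <- rbind(trace, data.frame(round = r, wells_tested = n_sub,
                                       positives = 0L,
                                       allele_frequency = 0))
      recovered <- "lost"
      break
    }
    score_hom <- vapply(subpops, function(s) {
      tot <- sum(s); if (tot == 0L) 0 else s[["hom"]] / tot
    }, numeric(1))
    score_car <- vapply(subpops, function(s) {
      tot <- sum(s); if (tot == 0L) 0 else (s[["het"]] + s[["hom"]]) / tot
    }, numeric(1))
    pick <- which(pos)[order(-score_hom[pos], -score_car[pos])][1L]
    pop <- subpops[[pick]]
    tot <- sum(pop)
    af <- if (tot == 0L) 0 else (pop[["het"]] / 2 + pop[["hom"]]) / tot
    trace <- rbind(trace, data.frame(round = r, wells_tested = n_sub,
                                     positives = sum(pos),
                                     allele_frequency = af))
    if (pop[["wt"]] == 0L && pop[["het"]] == 0L && pop[["hom"]] > 0L) {
      recovered <- "homozygous"
      break
    }
  }
  if (is.na(recovered)) {
    recovered <- if (pop[["het"]] + pop[["hom"]] > 0L)
      "persistent_heterozygous" else "lost"
  }
  structure(
    list(recovered = recovered, rounds = trace, reactions_used = reactions,
         final_population = pop),
    class = "screen_result"
  )
}

#' Simulate one complete screen
#'
#' Library construction, pooling, pool screening, addressing, and sib
#' selection on the first confirmed well, with full reaction accounting.
#'
#' @param sc a [screen_scenario()].
#' @param seed RNG seed for the whole run; runs are reproducible
#'   bit-for-bit given `(sc, seed)`.
#' @return a `"screen_result"` with fields `detected` (any positive pool),
#'   `addressed_well` (id or `NA`), `rounds` (sib trace), `recovered`,
#'   `reactions_used` (pools + addressing + sib tests),
#'   `pool_reactions`, `addressing_reactions`, `lost_at_addressing`,
#'   and `library_carrier_wells`.
#' @export
run_screen <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "screen_scenario"))
  if (!is.null(seed)) set.seed(seed)
  lib <- build_library(sc)
  grid <- pool_dna(lib)
  screened <- screen_pools(grid, sc)
  pool_rxn <- attr(screened, "reactions") %||% 0L
  detected <- any(screened$positive)
  addr <- list(confirmed = lib[0L, , drop = FALSE], candidates = 0L,
               reactions = 0L, lost_at_addressing = FALSE)
  if (detected) addr <- address_positive(screened, lib, sc)
  sib <- NULL
  recovered <- "lost"
  addressed_well <- NA_character_
  rounds <- data.frame(round = integer(), wells_tested = integer(),
                       positives = integer(), allele_frequency = numeric())
  if (nrow(addr$confirmed) > 0L) {
    # follow up the confirmed well with the most carriers
    w <- addr$confirmed[order(-addr$confirmed$mutants), , drop = FALSE][1L, ,
                                                                 drop = FALSE]
    if (w$mutants >= 1L) {
      addressed_well <- w$well_id
      sib <- run_sib_selection(w, sc)
      recovered <- sib$recovered
      rounds <- sib$rounds
    }
  }
  structure(
    list(detected = detected, addressed_well = addressed_well,
         rounds = rounds, recovered = recovered,
         reactions_used = pool_rxn + addr$reactions +
           (if (is.null(sib)) 0L else sib$reactions_used),
         pool_reactions = pool_rxn,
         addressing_reactions = addr$reactions,
         lost_at_addressing = isTRUE(addr$lost_at_addressing),
         library_carrier_wells = sum(lib$mutants > 0L)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> detected = %s, well = %s, recovered = %s\n",
              x$detected %||% NA, x$addressed_well %||% NA, x$recovered))
  if (!is.null(x$reactions_used)) {
    cat(sprintf("  reactions used: %d\n", x$reactions_used))
  }
  if (nrow(x$rounds) > 0L) {
    cat("  sib rounds:\n")
    print(x$rounds, row.names = FALSE)
  }
  invisible(x)
}

#' Reaction accounting for a completed screen
#'
#' Pooling exists to reduce reaction count: a plate of `rows x cols` wells
#' needs only `rows + cols` pool reactions (x2 in duplicate) instead of one
#' per well. This report reconciles the run's trace against that arithmetic
#' and against the no-pooling baseline of one reaction per well.
#'
#' @param result a `"screen_result"` from [run_screen()].
#' @param sc the [screen_scenario()] it was run under.
#' @return list with `pool_reactions`, `addressing_reactions`,
#'   `sib_reactions`, `total`, and `baseline_no_pooling` (= `n_wells`).
#' @export
count_reactions <- function(result, sc) {
  stopifnot(inherits(result, "screen_result"),
            inherits(sc, "screen_scenario"))
  sib_rxn <- sum(result$rounds$wells_tested)
  total <- result$pool_reactions + result$addressing_reactions + sib_rxn
  stopifnot(total == result$reactions_used)
  list(pool_reactions = result$pool_reactions,
       addressing_reactions = result$addressing_reactions,
       sib_reactions = sib_rxn,
       total = total,
       baseline_no_pooling = sc$n_wells)
}
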