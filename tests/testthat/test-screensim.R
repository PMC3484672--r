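test_that("scenario validation rejects inconsistent configurations", {
  expect_error(screen_scenario(genomes_per_well = 0),
               class = "delscreen_config_error")
  expect_error(screen_scenario(pcr_sensitivity = 0),
               class = "delscreen_config_error")
  expect_error(screen_scenario(deletion_rate_per_target = 2),
               class = "delscreen_config_error")
  # seed densities must fall to single-parent picks
  expect_error(screen_scenario(sib_plan = c(24, 24), sib_seed_worms = c(1, 10)),
               class = "delscreen_config_error")
  expect_error(screen_scenario(sib_plan = c(24, 24), sib_seed_worms = c(10, 5)),
               class = "delscreen_config_error")
  sc <- screen_scenario()
  expect_identical(sc$n_wells, 960L)
})

test_that("library construction matches the binomial carrier model", {
  sc0 <- screen_scenario(plates = 2, deletion_rate_per_target = 0)
  set.seed(1)
  expect_identical(sum(build_library(sc0)$mutants), 0L)
  sc1 <- screen_scenario(plates = 2, deletion_rate_per_target = 1)
  lib1 <- build_library(sc1)
  expect_true(all(lib1$mutants == lib1$genomes))
  # total mutants within 4 sigma of W*G*r
  r <- 1e-3
  scr <- screen_scenario(plates = 5, genomes_per_well = 200,
                         deletion_rate_per_target = r)
  set.seed(42)
  tot <- sum(build_library(scr)$mutants)
  n <- scr$n_wells * scr$genomes_per_well
  expect_lt(abs(tot - n * r), 4 * sqrt(n * r * (1 - r)))
})

test_that("grid pooling conserves mutant mass and addresses single wells", {
  sc <- screen_scenario(plates = 1, deletion_rate_per_target = 0,
                        pcr_sensitivity = 1)
  set.seed(2)
  lib <- build_library(sc)
  grid <- pool_dna(lib)
  expect_identical(nrow(grid), 20L)  # 8 rows + 12 cols
  expect_identical(sum(grid$axis == "row"), 8L)
  expect_identical(sum(grid$axis == "col"), 12L)
  # plant one mutant well: exactly one positive row and one positive column
  lib$mutants[29] <- 10L
  grid <- pool_dna(lib)
  scr <- screen_pools(grid, sc)
  expect_identical(sum(scr$positive & scr$axis == "row"), 1L)
  expect_identical(sum(scr$positive & scr$axis == "col"), 1L)
  expect_identical(scr$index[scr$positive & scr$axis == "row"], lib$row[29])
  expect_identical(scr$index[scr$positive & scr$axis == "col"], lib$col[29])
  # mutant mass conservation between the two axes: weighting each pool's
  # template fraction by its genome count recovers the library total
  expect_equal(sum(grid$fraction[grid$axis == "row"] *
                     grid$genomes[grid$axis == "row"]),
               sum(grid$fraction[grid$axis == "col"] *
                     grid$genomes[grid$axis == "col"]))
  expect_equal(sum(grid$mutants[grid$axis == "row"]), sum(lib$mutants))
  expect_equal(sum(grid$mutants[grid$axis == "col"]), sum(lib$mutants))
})

test_that("pool screening is perfectly specific and duplicate-OR sensitive", {
  sc <- screen_scenario(plates = 1, deletion_rate_per_target = 0)
  # mutant-free samples never fire, over many seeded attempts
  set.seed(3)
  fired <- replicate(10000, test_sample(0, sc)$positive)
  expect_identical(sum(fired), 0L)
  # one template, s = 0.5, duplicate OR: closed form 1 - (1-s)^2 = 0.75
  set.seed(4)
  hits <- replicate(10000, pcr_reaction(1, 0.5) || pcr_reaction(1, 0.5))
  expect_equal(mean(hits), 0.75, tolerance = 0.02)
  # s = 1: any carrier-containing sample fires
  sc1 <- screen_scenario(plates = 1, pcr_sensitivity = 1)
  set.seed(5)
  expect_true(all(replicate(200, test_sample(1e-4, sc1)$positive)))
})

test_that("addressing intersects positive rows and columns per plate", {
  sc <- screen_scenario(plates = 1, deletion_rate_per_target = 0,
                        pcr_sensitivity = 1)
  set.seed(6)
  lib <- build_library(sc)
  lib$mutants[c(1)] <- 5L
  scr <- screen_pools(pool_dna(lib), sc)
  addr <- address_positive(scr, lib, sc)
  expect_identical(addr$candidates, 1L)
  expect_identical(nrow(addr$confirmed), 1L)
  expect_identical(addr$confirmed$well_id, lib$well_id[1])
  expect_false(addr$lost_at_addressing)
  # two mutant wells in distinct rows and columns: 2x2 = 4 candidates
  lib2 <- build_library(sc)
  lib2$mutants[lib2$row == 2 & lib2$col == 3] <- 5L
  lib2$mutants[lib2$row == 5 & lib2$col == 7] <- 5L
  scr2 <- screen_pools(pool_dna(lib2), sc)
  addr2 <- address_positive(scr2, lib2, sc)
  expect_identical(addr2$candidates, 4L)
  expect_lte(nrow(addr2$confirmed), 4L)
  expect_identical(sort(addr2$confirmed$mutants), c(5L, 5L))
})

test_that("a pool false negative raises the lost-at-addressing flag", {
  sc <- screen_scenario(plates = 1, deletion_rate_per_target = 0,
                        pcr_sensitivity = 1)
  set.seed(7)
  lib <- build_library(sc)
  lib$mutants[29] <- 5L
  scr <- screen_pools(pool_dna(lib), sc)
  # force the column pool dark, as a sub-sensitive PCR would
  scr$positive[scr$axis == "col"] <- FALSE
  addr <- address_positive(scr, lib, sc)
  expect_identical(nrow(addr$confirmed), 0L)
  expect_true(addr$lost_at_addressing)
})

test_that("selfing follows Mendelian segregation, with and without lethality", {
  set.seed(8)
  off <- self_generation(c(wt = 0L, het = 1L, hom = 0L),
                         brood_factor = 10000)
  expect_gt(chisq.test(off, p = c(1, 2, 1) / 4)$p.value, 0.01)
  # recessive lethal: homozygotes removed, surviving adults 1 wt : 2 het
  off_l <- self_generation(c(wt = 0L, het = 1L, hom = 0L),
                           brood_factor = 10000, lethal = TRUE)
  expect_identical(off_l[["hom"]], 0L)
  expect_gt(chisq.test(off_l[c("wt", "het")], p = c(1, 2) / 3)$p.value, 0.01)
  # het fraction halves every selfing generation (no selection)
  pop <- c(wt = 0L, het = 40000L, hom = 0L)
  for (g in 1:4) {
    pop <- self_generation(pop, brood_factor = 100, max_pop = 4e4)
    het_frac <- pop[["het"]] / sum(pop)
    expect_lt(abs(het_frac - 0.5^g), 4 * sqrt(0.5^g * (1 - 0.5^g) / 4e4))
  }
})

test_that("sib selection recovers homozygotes only for viable targets", {
  sc_l <- screen_scenario(plates = 1, genomes_per_well = 500,
                          pcr_sensitivity = 1, lethal = TRUE)
  sc_v <- screen_scenario(plates = 1, genomes_per_well = 500,
                          pcr_sensitivity = 1, lethal = FALSE)
  well <- data.frame(well_id = "P01-A01", plate = 1L, row = 1L, col = 1L,
                     genomes = 500L, mutants = 500L)
  res_l <- sapply(1:30, function(i) {
    set.seed(i); run_sib_selection(well, sc_l)$recovered
  })
  expect_false(any(res_l == "homozygous"))
  expect_true(all(res_l %in% c("persistent_heterozygous", "lost")))
  res_v <- sapply(1:30, function(i) {
    set.seed(i); run_sib_selection(well, sc_v)$recovered
  })
  expect_true(any(res_v == "homozygous"))
  # carrier-free wells are a config error
  well0 <- well; well0$mutants <- 0L
  expect_error(run_sib_selection(well0, sc_v),
               class = "delscreen_config_error")
})

test_that("reaction accounting matches the pooling arithmetic", {
  # 10 duplicate-screened plates with no hits: 10 x (8+12) x 2 = 400,
  # against a 960-reaction no-pooling baseline
  sc <- screen_scenario(plates = 10, deletion_rate_per_target = 0)
  res <- run_screen(sc, seed = 9)
  rep <- count_reactions(res, sc)
  expect_identical(rep$pool_reactions, 400L)
  expect_identical(rep$total, 400L)
  expect_identical(rep$baseline_no_pooling, 960L)
  expect_lt(rep$total, rep$baseline_no_pooling)
  # zero plates: zero reactions
  sc0 <- screen_scenario(plates = 0, deletion_rate_per_target = 0)
  expect_identical(count_reactions(run_screen(sc0, seed = 1), sc0)$total, 0L)
  # single plate, one all-carrier well, lethal target, s = 1: the full path
  # runs 40 pool + 1 addressing + 24 x 3 sib reactions = 113
  sc1 <- screen_scenario(plates = 1, genomes_per_well = 500,
                         deletion_rate_per_target = 0, pcr_sensitivity = 1,
                         lethal = TRUE, sib_plan = c(24, 24, 24),
                         sib_seed_worms = c(10, 1, 1))
  set.seed(10)
  lib <- build_library(sc1)
  lib$mutants[37] <- 500L
  scr <- screen_pools(pool_dna(lib), sc1)
  addr <- address_positive(scr, lib, sc1)
  sib <- run_sib_selection(addr$confirmed[1, ], sc1)
  expect_identical(attr(scr, "reactions"), 40L)
  expect_identical(addr$reactions, 1L)
  expect_identical(sib$reactions_used, 72L)
  expect_identical(sum(sib$rounds$wells_tested), 72L)
})

test_that("perfect duplicate screening never misses a carrier library", {
  sc <- function(s) screen_scenario(plates = 2, genomes_per_well = 200,
                                    deletion_rate_per_target = 5e-5,
                                    pcr_sensitivity = s)
  carriers <- 0L
  for (i in 1:60) {
    r <- run_screen(sc(1), seed = i)
    if (r$library_carrier_wells > 0) {
      carriers <- carriers + 1L
      expect_true(r$detected)
    }
  }
  expect_gt(carriers, 10L)  # the condition was actually exercised
})

test_that("screen detection is monotone in PCR sensitivity", {
  p_detect <- function(s) {
    sc <- screen_scenario(plates = 2, genomes_per_well = 200,
                          deletion_rate_per_target = 5e-5,
                          pcr_sensitivity = s)
    hits <- 0L; n <- 0L
    for (i in 1:120) {
      r <- run_screen(sc, seed = i)
      if (r$library_carrier_wells > 0) {
        n <- n + 1L
        hits <- hits + r$detected
      }
    }
    hits / n
  }
  rates <- vapply(c(0.05, 0.3, 1), p_detect, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_identical(rates[3], 1)
})

test_that("simulated screens are reproducible bit-for-bit per seed", {
  sc <- screen_scenario(plates = 1, deletion_rate_per_target = 1e-4)
  r1 <- run_screen(sc, seed = 123)
  r2 <- run_screen(sc, seed = 123)
  expect_identical(r1, r2)
  # different seeds change the stochastic outcome somewhere across runs
  rx <- vapply(1:20, function(i) run_screen(sc, seed = i)$reactions_used,
               integer(1))
  expect_gt(length(unique(rx)), 1L)
})
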