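test_that("decomposition enumeration finds exactly the valid placements", {
  # unique zero-insert placement
  d <- enumerate_decompositions("AAAACGTTTT", "AAAATTTT", k_min = 1,
                                max_insert = 0)
  expect_identical(nrow(d), 1L)
  expect_identical(d$left, 4L)
  expect_identical(d$right, 6L)
  # 3-bp microhomology "GCT": four equivalent placements
  d <- enumerate_decompositions("AAAGCTGCTTT", "AAAGCTTT", k_min = 1,
                                max_insert = 0)
  expect_identical(nrow(d), 4L)
  expect_setequal(d$left, 3:6)
  expect_identical(d$right, d$left + 3L)
  expect_identical(d$left[1], 6L)  # canonical (rightmost L) sorts first
  # unrelated product: no shared flank at all
  expect_error(
    enumerate_decompositions(paste0(strrep("A", 20), strrep("T", 20)),
                             "GGGG", k_min = 1),
    class = "delscreen_no_deletion")
  # anchors shorter than k_min are rejected
  expect_error(enumerate_decompositions("AAAACGTTTT", "AAAATTTT", k_min = 5),
               class = "delscreen_no_deletion")
  # a product at least as long as the amplicon is no deletion
  expect_error(enumerate_decompositions("ACGTACGT", "ACGTACGT", k_min = 1),
               class = "delscreen_no_deletion")
})

test_that("every enumerated decomposition reconstructs the product", {
  set.seed(5)
  for (i in 1:20) {
    aseq <- random_seq(30)
    L <- sample(0:20, 1); R <- L + sample(3:8, 1)
    ins <- if (i %% 3 == 0) random_seq(2) else ""
    prod <- paste0(substr(aseq, 1, L), ins, substr(aseq, R + 1, 30))
    d <- tryCatch(enumerate_decompositions(aseq, prod, k_min = 1),
                  delscreen_no_deletion = function(e) NULL)
    if (is.null(d)) next
    rebuilt <- paste0(substring(aseq, 1, d$left), d$insert,
                      substring(aseq, d$right + 1))
    expect_true(all(rebuilt == prod))
    expect_true(all(d$left < d$right))
  }
})

test_that("canonical calls match the reporting standard on hand cases", {
  amb <- call_breakpoint(bare_amplicon("AAAGCTGCTTT"), "AAAGCTTT", k_min = 1)
  expect_identical(amb$allele$break_class, "ambiguous")
  expect_identical(amb$allele$left, 6L)
  expect_identical(amb$allele$right, 9L)
  expect_identical(amb$allele$ambiguity_width, 4L)
  expect_identical(amb$flank_left, "AAAGCT")
  expect_identical(amb$flank_right, "TT")
  expect_identical(nrow(amb$all_placements), 4L)

  ins <- call_breakpoint(bare_amplicon("AAAACCCCGGGGTTTT"), "AAAATATTTT",
                         k_min = 1)
  expect_identical(ins$allele$break_class, "insertion")
  expect_identical(ins$allele$left, 4L)
  expect_identical(ins$allele$right, 12L)
  expect_identical(ins$allele$insert, "TA")
  expect_identical(ins$allele$ambiguity_width, 1L)

  cln <- call_breakpoint(bare_amplicon("AAAACGTTTT"), "AAAATTTT", k_min = 1)
  expect_identical(cln$allele$break_class, "clean")
  expect_identical(cln$allele$left, 4L)
  expect_identical(cln$allele$right, 6L)
  expect_identical(cln$allele$ambiguity_width, 1L)
})

test_that("caller agrees with the enumeration oracle on all planted events", {
  set.seed(91)
  total <- 0L
  for (alen in c(12L, 20L, 28L)) {
    total <- total + check_oracle_agreement(random_seq(alen),
                                            insert_lengths = 0:2)
  }
  expect_gt(total, 1500L)
})

test_that("normalization is idempotent and canonicalizes foreign placements", {
  amp <- bare_amplicon("AAAGCTGCTTT")
  rep1 <- call_breakpoint(amp, "AAAGCTTT", k_min = 1)
  rep2 <- normalize_report(rep1, amp)
  expect_identical(allele_fields(rep2$allele), allele_fields(rep1$allele))
  # a report built at the leftmost placement (L=3) normalizes to L=6
  leftmost <- rep1
  leftmost$allele <- deletion_allele("allele1", "amp", 3, 6,
                                     break_class = "ambiguous",
                                     ambiguity_width = 4)
  norm <- normalize_report(leftmost, amp)
  expect_identical(norm$allele$left, 6L)
  expect_identical(norm$allele$right, 9L)
  # an insert whose first base extends the left flank is absorbed into it
  amp2 <- bare_amplicon("AAAACGTTTT")
  shifted <- rep1
  shifted$allele <- deletion_allele("allele1", "amp", 3, 6, insert = "A",
                                    break_class = "insertion")
  # product AAA + A + TTTT == AAAATTTT: canonical form is the clean call
  norm2 <- normalize_report(shifted, amp2)
  expect_identical(norm2$allele$break_class, "clean")
  expect_identical(norm2$allele$left, 4L)
  expect_identical(norm2$allele$insert, "")
})

test_that("canonical insertion reports are flank-maximal", {
  set.seed(17)
  n_ins <- 0L
  for (s in 1:120) {
    pl <- planted_case(s, insertion_prob = 1)
    cb <- call_breakpoint(pl$amplicon, pl$product)
    a <- cb$allele
    expect_identical(a$break_class, "insertion")
    aseq <- pl$amplicon$seq
    expect_false(substr(a$insert, 1, 1) ==
                   substr(aseq, a$left + 1, a$left + 1))
    expect_false(substr(a$insert, nchar(a$insert), nchar(a$insert)) ==
                   substr(aseq, a$right, a$right))
    n_ins <- n_ins + 1L
  }
  expect_identical(n_ins, 120L)
})

test_that("ambiguity width equals microhomology length plus one", {
  probs_for <- function(h) { p <- rep(0, 11); p[h + 1] <- 1; p }
  for (h in c(0L, 1L, 3L, 6L)) {
    for (s in 1:25) {
      pl <- planted_case(s + 1000L * h, insertion_prob = 0,
                         microhomology_probs = probs_for(h))
      cb <- call_breakpoint(pl$amplicon, pl$product)
      expect_identical(cb$allele$ambiguity_width, h + 1L)
      expect_identical(cb$allele$break_class,
                       if (h == 0L) "clean" else "ambiguous")
    }
  }
})

test_that("read pairs merge into the product and reproduce the direct call", {
  pl <- planted_case(421)
  direct <- call_breakpoint(pl$amplicon, pl$product)
  np <- nchar(pl$product)
  # inward reads with a generous overlap
  rd <- make_reads(pl$product, read_len = ceiling(np * 0.7))
  from_reads <- call_from_reads(pl$amplicon, rd$left_read, rd$right_read)
  expect_identical(allele_fields(from_reads$allele),
                   allele_fields(direct$allele))
  # identity merge: both reads are the whole product
  rd2 <- make_reads(pl$product, read_len = np)
  from_full <- call_from_reads(pl$amplicon, rd2$left_read, rd2$right_read)
  expect_identical(allele_fields(from_full$allele),
                   allele_fields(direct$allele))
  # right read supplied already on the reference strand is auto-detected
  from_fwd <- call_from_reads(pl$amplicon, rd$left_read,
                              substring(pl$product, np - nchar(rd$right_read) + 1L))
  expect_identical(allele_fields(from_fwd$allele),
                   allele_fields(direct$allele))
})

test_that("read-based calling reports assembly and no-deletion failures", {
  pl <- planted_case(33, deletion_size_range = c(100L, 150L))
  aseq <- pl$amplicon$seq
  # reads of the intact amplicon: merged product equals the amplicon
  rd <- make_reads(aseq, read_len = nchar(aseq))
  expect_error(call_from_reads(pl$amplicon, rd$left_read, rd$right_read),
               class = "delscreen_no_deletion")
  # disjoint reads cannot be assembled
  np <- nchar(pl$product)
  left <- substr(pl$product, 1, 200)
  right_rc <- rc(substring(pl$product, np - 199))
  expect_error(call_from_reads(pl$amplicon, left, right_rc),
               class = "delscreen_assembly_error")
  # overlap mismatches above the threshold are a quality failure
  rd3 <- make_reads(pl$product, read_len = ceiling(np * 0.7),
                    error_rate = 0.05, seed = 9)
  expect_error(call_from_reads(pl$amplicon, rd3$left_read, rd3$right_read,
                               max_mismatch_rate = 0),
               class = "delscreen_low_quality")
})

test_that("called alleles always satisfy the allele invariants", {
  # cross-module property: the caller can only emit self-consistent alleles
  set.seed(7)
  for (s in 1:200) {
    pl <- planted_case(s + 5000L)
    a <- call_breakpoint(pl$amplicon, pl$product)$allele
    expect_s3_class(a, "deletion_allele")
    expect_true(a$left >= 0 && a$left < a$right &&
                  a$right <= nchar(pl$amplicon$seq))
    if (a$break_class == "insertion") expect_gte(nchar(a$insert), 1L)
    if (a$break_class == "ambiguous") expect_gte(a$ambiguity_width, 2L)
    if (a$break_class == "clean") {
      expect_identical(a$ambiguity_width, 1L)
      expect_identical(a$insert, "")
    }
    expect_identical(reconstruct_product(pl$amplicon, a), pl$product)
  }
})
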