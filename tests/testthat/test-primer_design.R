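test_that("nearest-neighbor Tm reproduces independent reference values", {
  # regression fixtures computed once with an independent implementation of
  # the same unified parameter set (50 mM monovalent, 400 nM total primer)
  ref <- c(ACCATCTGGGTGGAGAAAGTG = 56.487294,
           TGGCGGAAATGAACTCGTAAT = 54.928105,
           GATGGCACCAGCACAGG = 55.621413,
           GGAGCACGGCGACTATG = 55.249714,
           TCCCGAATCCGACTATGA = 51.677573,
           TCGCTGCCAACTACTAAAA = 51.692338,
           ACGTACGTACGTACGTACGT = 55.847844,
           GGGGCCCCGGGGCCCCAAAA = 69.125788)
  expect_equal(melting_temperature(names(ref)), unname(ref),
               tolerance = 1e-5)
})

test_that("Tm is duplex-symmetric and rises with 3' G/C extension", {
  set.seed(41)
  for (i in 1:25) {
    s <- rand_dna(sample(12:24, 1))
    expect_equal(melting_temperature(s), melting_temperature(rc_chr(s)),
                 tolerance = 1e-9)
    expect_gt(melting_temperature(paste0(s, sample(c("G", "C"), 1))),
              melting_temperature(s))
  }
  expect_error(melting_temperature("ACGTNACGTA"), "A/C/G/T")
  expect_error(melting_temperature("ACGTACG"), "at least 8")
})

test_that("the primer validator reports length and alphabet", {
  v <- validate_primer("ACCATCTGGGTGGAGAAAGTG")
  expect_equal(v$length, 21L)
  expect_equal(v$gc, mean(strsplit(v$seq, "")[[1]] %in% c("G", "C")))
  expect_error(validate_primer("ACGTN"), "non-A/C/G/T")
})

test_that("enumeration respects constraints and is deterministic", {
  expect_error(enumerate_pairs(strrep("ACGT", 20)), "shorter than")
  set.seed(42)
  marker <- marker_candidate("S", "m", rand_dna(600))
  p1 <- enumerate_pairs(marker)
  p2 <- enumerate_pairs(marker)
  expect_identical(p1, p2)
  if (nrow(p1)) {
    cs <- primer_constraints()
    expect_true(all(nchar(p1$fwd_seq) >= cs$primer_len[1] &
                    nchar(p1$fwd_seq) <= cs$primer_len[2]))
    expect_true(all(p1$product_len >= cs$product_len[1] &
                    p1$product_len <= cs$product_len[2]))
    expect_true(all(p1$fwd_tm >= cs$tm_range[1] & p1$fwd_tm <= cs$tm_range[2]))
    expect_true(all(abs(p1$fwd_tm - p1$rev_tm) <= cs$max_dtm))
    expect_true(!is.unsorted(p1$penalty))
  }
})

test_that("a marker built around one admissible window pair returns it", {
  f <- "ACCGTCAGCATGGCTGACCT"
  r <- "TGGCAGTCCATCGTGACGTA"
  marker <- paste0(f, strrep("AT", 40), rc_chr(r))
  cs <- primer_constraints(primer_len = c(20L, 20L),
                           product_len = c(120L, 120L),
                           tm_range = c(58, 62), gc_range = c(0.55, 0.65))
  pp <- enumerate_pairs(marker, cs)
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$fwd_seq, f)
  expect_equal(pp$rev_seq, r)
  expect_equal(pp$product_len, 120L)
})

test_that("in-silico PCR finds the constructive amplicon and honors 3' rules", {
  fwd <- "ACCATCTGGGTGGAGAAAGTG"
  rev <- "TGGCGGAAATGAACTCGTAAT"
  template <- paste0(fwd, strrep("A", 73), rc_chr(rev))
  hits <- in_silico_pcr(list(fwd_seq = fwd, rev_seq = rev),
                        list(wrap_genome("T", template)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$product_len, 115L)

  # no primer k-mers at all: no amplification
  none <- in_silico_pcr(list(fwd_seq = fwd, rev_seq = rev),
                        list(wrap_genome("N", strrep("AC", 500))))
  expect_equal(nrow(none), 0L)

  # one mismatch inside the 3'-exact window kills the site ...
  t2 <- template
  substr(t2, 20, 20) <- if (substr(t2, 20, 20) == "A") "C" else "A"
  expect_equal(nrow(in_silico_pcr(list(fwd_seq = fwd, rev_seq = rev),
                                  list(wrap_genome("T", t2)))), 0L)
  # ... while the same mismatch at the primer 5' end is tolerated
  t3 <- template
  substr(t3, 1, 1) <- if (substr(t3, 1, 1) == "A") "C" else "A"
  h3 <- in_silico_pcr(list(fwd_seq = fwd, rev_seq = rev),
                      list(wrap_genome("T", t3)))
  expect_equal(nrow(h3), 1L)
  expect_equal(h3$fwd_mismatches, 1L)

  # marker integrated in the opposite orientation still amplifies
  h4 <- in_silico_pcr(list(fwd_seq = fwd, rev_seq = rev),
                      list(wrap_genome("T", rc_chr(template))))
  expect_equal(nrow(h4), 1L)
  expect_equal(h4$product_len, 115L)
})

test_that("specificity certification demands exactly one target amplicon", {
  fwd <- "ACCATCTGGGTGGAGAAAGTG"
  rev <- "TGGCGGAAATGAACTCGTAAT"
  amplicon <- paste0(fwd, strrep("A", 73), rc_chr(rev))
  pair <- list(fwd_seq = fwd, rev_seq = rev, product_len = 115L)
  set.seed(43)
  target <- wrap_genome("T", paste0(rand_dna(400), amplicon, rand_dna(400)))
  clean1 <- wrap_genome("O1", rand_dna(1200))
  clean2 <- wrap_genome("O2", rand_dna(1200))

  cert <- certify_specificity(pair, "T", list(target, clean1, clean2))
  expect_true(cert$pass)
  expect_equal(cert$amplicons$product_len, 115L)

  # duplicated marker in the target: two amplicons, fail
  dup <- wrap_genome("T", paste0(amplicon, rand_dna(300), amplicon))
  expect_false(certify_specificity(pair, "T", list(dup, clean1))$pass)

  # off-target amplicon: fail
  off <- wrap_genome("O1", paste0(rand_dna(100), amplicon, rand_dna(100)))
  expect_false(certify_specificity(pair, "T", list(target, off))$pass)

  expect_error(certify_specificity(pair, "Z", list(target)), "not among")
})

test_that("certified designs match their designed product length", {
  sim <- small_sim()
  mat <- small_matrix()
  cands <- lapply(candidates_for(sim$genomes, mat, "SIM02"),
                  screen_inhouse, genomes = sim$genomes)
  mk <- select_markers(cands)[[1]]
  des <- design_primers(mk, sim$genomes)
  expect_false(is.null(des$pair))
  expect_true(des$certification$pass)
  on_target <- des$certification$amplicons
  expect_equal(on_target$genome_id, "SIM02")
  expect_equal(on_target$product_len, des$pair$product_len)
})
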