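test_that("a fixed seed reproduces the collection byte for byte", {
  cfg <- sim_config(n_genomes = 4, core_families = 10, shell_families = 0,
                    cloud_families = 0, unique_per_genome = 2, seed = 7)
  s1 <- simulate_collection(cfg)
  s2 <- simulate_collection(cfg)
  expect_identical(lapply(s1$genomes, `[[`, "contigs"),
                   lapply(s2$genomes, `[[`, "contigs"))
  expect_identical(s1$truth, s2$truth)
})

test_that("the zero-mutation limit yields identical core genes everywhere", {
  cfg <- sim_config(n_genomes = 5, core_families = 50, shell_families = 0,
                    cloud_families = 0, unique_per_genome = 3,
                    core_snp_rate = 0, seed = 11)
  sim <- simulate_collection(cfg)
  genes <- do.call(rbind, lapply(sim$genomes, `[[`, "genes"))
  core <- genes[grepl("^core_", genes$annotation), ]
  per_family <- split(core$nt_seq, core$annotation)
  expect_length(per_family, 50L)
  expect_true(all(vapply(per_family, function(x)
    length(x) == 5L && length(unique(x)) == 1L, logical(1))))
  expect_true(all(sim$truth$distances == 0))
})

test_that("planted unique genes share no 15-mer with any other gene", {
  sim <- small_sim()
  genes <- do.call(rbind, lapply(sim$genomes, `[[`, "genes"))
  uniq_tags <- unlist(sim$truth$unique_tags)
  kmers <- function(s) {
    n <- nchar(s)
    if (n < 15) character() else substring(s, 1:(n - 14), 15:n)
  }
  other <- genes$nt_seq[!genes$gene_tag %in% uniq_tags]
  other_km <- unique(unlist(lapply(other, function(s)
    c(kmers(s), kmers(rc_chr(s))))))
  for (tag in uniq_tags) {
    u <- genes$nt_seq[genes$gene_tag == tag]
    expect_length(intersect(kmers(u), other_km), 0L)
  }
  # and none shared between distinct unique genes
  uk <- lapply(uniq_tags, function(tag) {
    s <- genes$nt_seq[genes$gene_tag == tag]
    c(kmers(s), kmers(rc_chr(s)))
  })
  for (i in seq_along(uk))
    for (j in seq_along(uk))
      if (i < j) expect_length(intersect(uk[[i]], uk[[j]]), 0L)
})

test_that("truth SNP distances equal a brute-force column census", {
  sim <- small_sim()
  genes <- do.call(rbind, lapply(sim$genomes, function(g)
    cbind(g$genes, genome_id = g$genome_id)))
  ids <- vapply(sim$genomes, `[[`, character(1), "genome_id")
  core <- genes[grepl("^core_", genes$annotation), ]
  D <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (fam in unique(core$annotation)) {
    sub <- core[core$annotation == fam, ]
    M <- do.call(rbind, strsplit(sub$nt_seq[match(ids, sub$genome_id)], ""))
    n_alleles <- apply(M, 2, function(col) length(unique(col)))
    keep <- which(n_alleles == 2L)
    for (i in seq_along(ids)) for (j in seq_along(ids))
      if (i < j) {
        d <- sum(M[i, keep] != M[j, keep])
        D[i, j] <- D[i, j] + d; D[j, i] <- D[j, i] + d
      }
  }
  expect_identical(unname(D), unname(sim$truth$distances))
})

test_that("carriage bands keep accessory families off the unique edge", {
  sim <- small_sim()
  carriers <- vapply(sim$truth$carriage, length, integer(1))
  fam <- sim$truth$families
  shell_k <- carriers[fam$family[fam$category == "shell"]]
  expect_true(all(shell_k >= 2 & shell_k / 5 >= 0.15 & shell_k / 5 < 0.95))
  expect_true(all(carriers[fam$family[fam$category == "unique"]] == 1L))
  # cloud families need a wide enough collection for >= 2 carriers below 15%
  expect_error(sim_config(n_genomes = 10, cloud_families = 5),
               "cloud")
})

test_that("simulated qPCR tables follow the linear model exactly at zero noise", {
  expect_error(simulate_qpcr(3.4, 38, levels = 3:7), "negative")
  tab <- simulate_qpcr(-3.4789, 38.217, levels = 3:7, replicates = 2,
                       noise_sd = 0, seed = 1)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$ct[tab$log10_cfu == 5][1], 20.8225, tolerance = 1e-12)
  # collinear: residuals of an exact line are zero
  fit <- lm(ct ~ log10_cfu, data = tab)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("refitting a noisy dilution series recovers the slope", {
  tab <- simulate_qpcr(-3.4789, 38.217, levels = 3:7, replicates = 3,
                       noise_sd = 0.2, seed = 1)
  fit <- lm(ct ~ log10_cfu, data = tab)
  se <- summary(fit)$coefficients["log10_cfu", "Std. Error"]
  expect_lt(abs(coef(fit)[["log10_cfu"]] - (-3.4789)), 3 * se)
})
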