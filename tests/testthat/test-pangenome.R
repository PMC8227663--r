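toy_genome <- function(id, aa_list) {
  # wrap protein sequences in a minimal genome; nt fields are placeholders
  # of matching length so avg_nt_len stays meaningful
  genes <- data.frame(
    gene_tag = sprintf("%s_%03d", id, seq_along(aa_list)),
    contig_id = "c1", start = 1L, end = 3L, strand = "+",
    nt_seq = strrep("ACG", nchar(aa_list)),
    aa_seq = unlist(aa_list), annotation = "", stringsAsFactors = FALSE)
  genes$end <- nchar(genes$nt_seq)
  contig <- strrep("A", max(genes$end))
  annotated_genome(id, c(c1 = contig), genes)
}

rand_aa <- function(n) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")
}

test_that("identical proteins co-cluster and unrelated ones stay apart", {
  set.seed(1)
  p <- rand_aa(200); q <- rand_aa(180)
  g1 <- toy_genome("g1", list(p, q))
  g2 <- toy_genome("g2", list(p))
  cl <- cluster_genes(list(g1, g2))
  expect_length(cl, 2L)
  sizes <- sort(vapply(cl, function(x) nrow(x$members), integer(1)))
  expect_equal(sizes, c(1L, 2L))
  shared <- cl[[which(vapply(cl, function(x) nrow(x$members) == 2L,
                             logical(1)))]]
  expect_setequal(shared$members$genome_id, c("g1", "g2"))
})

test_that("greedy centroid rule chains via the longest founder", {
  # A-B and A-C above threshold, B-C below: one cluster via centroid A
  set.seed(21)
  A <- rand_aa(200)
  mutate_aa <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(x)
      sample(setdiff(c("A", "C", "D", "E", "F", "G"), x), 1L), character(1))
    paste(ch, collapse = "")
  }
  B <- mutate_aa(A, 1:12)            # identity to A = 188/200 = 0.94
  C <- mutate_aa(A, 189:200)         # identity to A = 0.94, to B = 0.88
  # independent identity oracle: column-wise comparison (equal lengths,
  # substitutions only, so the optimal alignment is gapless)
  col_id <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    mean(cx == cy)
  }
  expect_gte(col_id(A, B), 0.90)
  expect_gte(col_id(A, C), 0.90)
  expect_lt(col_id(B, C), 0.90)
  cl <- cluster_genes(list(toy_genome("g1", list(A)),
                           toy_genome("g2", list(B)),
                           toy_genome("g3", list(C))))
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]$members), 3L)
})

test_that("exact comparison at identity 1 reproduces hash grouping", {
  set.seed(5)
  seqs <- c(replicate(6, rand_aa(60)))
  pool <- sample(seqs, 30, replace = TRUE)
  genomes <- lapply(1:3, function(i)
    toy_genome(paste0("g", i), as.list(pool[((i - 1) * 10 + 1):(i * 10)])))
  cl <- cluster_genes(genomes, min_identity = 1)
  got <- sort(vapply(cl, function(x) nrow(x$members), integer(1)))
  want <- sort(unname(table(pool)))
  expect_equal(got, as.integer(want))
})

test_that("presence matrix collapses paralogs and rejects unknown genomes", {
  cl <- gene_cluster("f1", data.frame(genome_id = c("g1", "g1"),
                                      gene_tag = c("a", "b")), "a", 300)
  m <- build_matrix(list(cl), c("g1", "g2", "g3"))
  expect_equal(unname(rowSums(m$incidence)), 1)
  expect_equal(unname(m$incidence[1, ]), c(TRUE, FALSE, FALSE))
  expect_error(build_matrix(list(cl), c("g2", "g3")), "unknown genome")
})

test_that("partition bands follow the published carriage thresholds", {
  N <- 205L
  ks <- c(1L, 2L, 30L, 100L, 195L, 199L, 204L, 205L)
  inc <- matrix(FALSE, length(ks), N,
                dimnames = list(sprintf("f%d", seq_along(ks)), NULL))
  for (i in seq_along(ks)) inc[i, seq_len(ks[i])] <- TRUE
  colnames(inc) <- sprintf("g%03d", seq_len(N))
  clusters <- lapply(seq_along(ks), function(i)
    gene_cluster(sprintf("f%d", i),
                 data.frame(genome_id = colnames(inc)[seq_len(ks[i])],
                            gene_tag = sprintf("t%d_%d", i, seq_len(ks[i]))),
                 "t", 100))
  part <- partition(presence_absence_matrix(colnames(inc), clusters, inc))
  expect_equal(as.character(unname(part$category)),
               c("unique", "cloud", "cloud", "shell", "soft_core",
                 "soft_core", "core", "core"))
  expect_equal(sum(part$counts), length(ks))
})

test_that("unique gene lookup is column-order invariant and exact", {
  sim <- small_sim()
  mat <- small_matrix()
  for (g in c("SIM01", "SIM04")) {
    ug <- unique_genes(mat, g)
    tags <- sort(vapply(ug, function(cl)
      cl$members$gene_tag[cl$members$genome_id == g][1], character(1)))
    expect_identical(tags, sort(sim$truth$unique_tags[[g]]))
  }
  perm <- c(3, 1, 5, 2, 4)
  mat_p <- presence_absence_matrix(mat$genome_ids[perm], mat$clusters,
                                   mat$incidence[, perm])
  u1 <- vapply(unique_genes(mat, "SIM02"), `[[`, character(1), "cluster_id")
  u2 <- vapply(unique_genes(mat_p, "SIM02"), `[[`, character(1), "cluster_id")
  expect_identical(u1, u2)
  expect_error(unique_genes(mat, "nope"), "unknown genome")
})

test_that("rarefaction prefixes are monotone and anchored at m = 1", {
  mat <- small_matrix()
  cur <- rarefaction(mat, n_orderings = 20, seed = 9)
  expect_true(all(diff(cur$mean_total) >= 0))
  expect_true(all(diff(cur$mean_conserved) <= 0))
  expect_equal(cur$mean_total[1], cur$mean_conserved[1])
  expect_gte(cur$mean_total[1], min(colSums(mat$incidence)))
  expect_lte(cur$mean_total[1], max(colSums(mat$incidence)))
  # deterministic under seed
  expect_identical(cur, rarefaction(mat, n_orderings = 20, seed = 9))
})
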