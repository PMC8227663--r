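snp_fixture <- function(seqs) {
  # one shared core gene per genome, sequences differing by substitutions
  genomes <- lapply(names(seqs), function(id) {
    genes <- data.frame(gene_tag = paste0(id, "_001"), contig_id = "c1",
                        start = 1L, end = nchar(seqs[[id]]), strand = "+",
                        nt_seq = seqs[[id]],
                        aa_seq = strainmark:::translate_cds(seqs[[id]]),
                        annotation = "core", stringsAsFactors = FALSE)
    annotated_genome(id, setNames(seqs[[id]], "c1"), genes)
  })
  ids <- names(seqs)
  mat <- build_matrix(cluster_genes(genomes), ids)
  list(genomes = genomes, mat = mat, part = partition(mat))
}

test_that("only ungapped bi-allelic columns are retained", {
  base <- paste0("ATG", strrep("GCA", 20), "TAA")   # 66 bp
  s2 <- base; substr(s2, 11, 11) <- "T"   # C -> T: bi-allelic, kept
  s3 <- base; substr(s3, 22, 22) <- "T"   # ref G, s3 T, s4 C: tri-allelic
  s4 <- base; substr(s4, 22, 22) <- "C"
  fx <- snp_fixture(list(r = base, b = s2, c = s3, d = s4))
  aln <- call_core_snps(fx$genomes, fx$mat, fx$part, reference = "r")
  expect_equal(nrow(aln$sites), 1L)
  expect_equal(aln$sites$ref_pos, 11L)
  expect_equal(unname(nchar(aln$alleles)), rep(1L, 4))
})

test_that("identical genomes give zero sites and zero distances", {
  base <- paste0("ATG", strrep("CGT", 25), "TAA")
  fx <- snp_fixture(list(a = base, b = base, c = base))
  aln <- call_core_snps(fx$genomes, fx$mat, fx$part, reference = "a")
  expect_equal(nrow(aln$sites), 0L)
  expect_true(all(snp_distances(aln) == 0))
})

test_that("distances are Hamming on concatenated alleles and metric", {
  aln <- structure(list(genome_ids = c("a", "b"),
                        alleles = c(a = "AAG", b = "ACG"),
                        sites = data.frame(family = "f", ref_pos = 1:3),
                        reference = "a"),
                   class = "core_snp_alignment")
  expect_equal(unname(snp_distances(aln)["a", "b"]), 1L)

  set.seed(8)
  n <- 6L; L <- 40L
  alleles <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "G"), L, TRUE), collapse = ""), character(1))
  aln <- structure(list(genome_ids = letters[1:n],
                        alleles = setNames(alleles, letters[1:n]),
                        sites = data.frame(family = "f", ref_pos = 1:L),
                        reference = "a"),
                   class = "core_snp_alignment")
  D <- snp_distances(aln)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D[i, j], D[i, k] + D[k, j])
})

test_that("pipeline distances reproduce the simulator truth", {
  sim <- small_sim()
  mat <- small_matrix()
  aln <- call_core_snps(sim$genomes, mat, partition(mat), reference = "SIM01")
  D <- snp_distances(aln)
  expect_identical(unname(D), unname(sim$truth$distances))
  # input order invariance
  aln2 <- call_core_snps(rev(sim$genomes), mat, partition(mat),
                         reference = "SIM01")
  expect_identical(snp_distances(aln2), D)
})

test_that("neighbor joining is exact on additive matrices", {
  t4 <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):0);")
  D4 <- ape::cophenetic.phylo(t4)[letters[1:4], letters[1:4]]
  rec <- nj_tree(D4)
  expect_setequal(rec$tip.label, letters[1:4])
  expect_lt(max(abs(ape::cophenetic.phylo(rec)[letters[1:4], letters[1:4]] -
                    D4)), 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(t4), rec), 0,
               ignore_attr = TRUE)
})

test_that("neighbor joining agrees with the reference implementation", {
  set.seed(13)
  t0 <- ape::rtree(8)
  D <- ape::cophenetic.phylo(t0)
  mine <- nj_tree(D)
  ref <- ape::nj(D)
  expect_lt(max(abs(ape::cophenetic.phylo(mine)[rownames(D), rownames(D)] -
                    D)), 1e-8)
  expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
})

test_that("degenerate and invalid distance inputs are rejected", {
  d <- matrix(c(0, 6, 6, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$edge.length), c(3, 3))
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(matrix(0, 1, 1)), "at least 2")
})
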