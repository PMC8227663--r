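test_that("CDS extraction follows 1-based inclusive coordinates and strand", {
  files <- write_toy_genome_files(
    list(c1 = "ACGTACGTACGT"),
    c("c1\ttoy\tCDS\t1\t6\t.\t+\t0\tlocus_tag=g1",
      "c1\ttoy\tCDS\t1\t6\t.\t-\t0\tlocus_tag=g2"))
  g <- read_genome(files$fasta, files$gff, genome_id = "toy")
  expect_equal(g$genes$nt_seq[g$genes$gene_tag == "g1"], "ACGTAC")
  expect_equal(g$genes$nt_seq[g$genes$gene_tag == "g2"], "GTACGT")
})

test_that("translation uses the bacterial table and drops the trailing stop", {
  files <- write_toy_genome_files(
    list(c1 = "ATGGCTAAATAAGGG"),
    "c1\ttoy\tCDS\t1\t12\t.\t+\t0\tlocus_tag=g1")
  g <- read_genome(files$fasta, files$gff, genome_id = "toy")
  expect_equal(g$genes$aa_seq, "MAK")
})

test_that("FASTA+GFF3 round-trips an annotated genome losslessly", {
  sim <- small_sim()
  g0 <- sim$genomes[[3]]
  fa <- tempfile(fileext = ".fna"); gf <- tempfile(fileext = ".gff")
  write_genome(g0, fa, gf)
  g1 <- read_genome(fa, gf, genome_id = g0$genome_id)
  expect_identical(g1$contigs, g0$contigs)
  for (col in c("gene_tag", "contig_id", "start", "end", "strand",
                "nt_seq", "aa_seq", "annotation"))
    expect_identical(g1$genes[[col]], g0$genes[[col]], label = col)
})

test_that("malformed genome inputs are hard errors naming the offender", {
  files <- write_toy_genome_files(
    list(c1 = "ACGTACGT"),
    "c1\ttoy\tCDS\t3\t20\t.\t+\t0\tlocus_tag=gX")
  expect_error(read_genome(files$fasta, files$gff), "gX")

  files <- write_toy_genome_files(
    list(c1 = "ACGTACGT"),
    "c1\ttoy\tCDS\t1\t6\t.\t?\t0\tlocus_tag=gY")
  expect_error(read_genome(files$fasta, files$gff), "strand")

  files <- write_toy_genome_files(
    list(c1 = "ACGTACGTACGT"),
    c("c1\ttoy\tCDS\t1\t6\t.\t+\t0\tlocus_tag=gZ",
      "c1\ttoy\tCDS\t4\t9\t.\t+\t0\tlocus_tag=gZ"))
  expect_error(read_genome(files$fasta, files$gff), "duplicate")

  files <- write_toy_genome_files(
    list(c1 = "ACGRACGT"),
    "c1\ttoy\tCDS\t1\t6\t.\t+\t0\tlocus_tag=gW")
  expect_error(read_genome(files$fasta, files$gff), "ambiguity")
})

test_that("presence/absence CSV round-trips and collapses paralog cells", {
  mat0 <- small_matrix()
  path <- tempfile(fileext = ".csv")
  write_presence_absence_csv(mat0, path)
  mat1 <- read_presence_absence_csv(path)
  expect_identical(mat1$genome_ids, mat0$genome_ids)
  expect_identical(unname(mat1$incidence), unname(mat0$incidence))
  norm_members <- function(m) {
    m <- m[order(m$genome_id, m$gene_tag), , drop = FALSE]
    rownames(m) <- NULL
    m
  }
  expect_equal(lapply(mat1$clusters, function(cl) norm_members(cl$members)),
               lapply(mat0$clusters, function(cl) norm_members(cl$members)))

  # paralog cell: two tab-separated tags are one presence
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    'Gene,"Non-unique Gene name",Annotation,g1,g2,g3',
    'fam1,,hyp,"tagA\ttagB",tagC,',
    'fam2,,hyp,,tagD,tagE'), csv)
  m <- read_presence_absence_csv(csv)
  expect_equal(sum(m$incidence), 4L)
  expect_equal(unname(rowSums(m$incidence)), c(2, 2))
  expect_equal(nrow(m$clusters[[1]]$members), 3L)  # paralogs kept as members
})

test_that("Roary statistic columns are skipped and ragged rows rejected", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    paste0('Gene,"Non-unique Gene name",Annotation,"No. isolates",',
           '"Avg group size nuc",gA,gB'),
    'f1,,x,2,431,t1,t2',
    'f2,,y,1,200,,t3'), csv)
  m <- read_presence_absence_csv(csv)
  expect_identical(m$genome_ids, c("gA", "gB"))
  expect_equal(m$clusters[[1]]$avg_nt_len, 431)
  expect_equal(sum(m$incidence), 3L)

  bad <- tempfile(fileext = ".csv")
  writeLines(c('Gene,"Non-unique Gene name",Annotation,gA,gB',
               'f1,,x,t1,t2', 'f2,,y,t3'), bad)
  expect_error(read_presence_absence_csv(bad), "ragged row 3")
})

test_that("marker table has the five published column roles, sorted by tag", {
  path <- tempfile(fileext = ".csv")
  write_marker_table(list(), path)
  df0 <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(df0), 0L)
  expect_identical(names(df0), c("Gene", "Non-Unique Gene Name", "Annotation",
                                 "Avg Group Size Nuc", "Gene Tag"))

  mk <- function(tag, len) {
    m <- marker_candidate("RG4-1", tag, strrep("A", 10))
    m$avg_nt_len <- len
    m
  }
  write_marker_table(list(mk("RG4-1_01875", 830), mk("RG4-1_01874", 1331),
                          mk("RG4-1_00079", 227)), path)
  df <- read.csv(path, check.names = FALSE)
  expect_equal(df[["Gene Tag"]],
               c("RG4-1_00079", "RG4-1_01874", "RG4-1_01875"))
  expect_equal(df[["Avg Group Size Nuc"]][df[["Gene Tag"]] == "RG4-1_01874"],
               1331)
})
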