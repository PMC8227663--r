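# Data model and file formats: annotated genomes (FASTA + GFF3), the Roary
# presence/absence CSV dialect, and the marker report table.
#
# Coordinates are GFF3-style 1-based inclusive at every user-facing boundary;
# the only 0-based half-open spans in the package are the alignment spans
# reported by the screening engine, which are documented as such.

#' Construct an annotated genome
#'
#' The central container of the pipeline: a set of contigs plus the gene
#' features annotated on them, with nucleotide and protein sequences
#' extracted per feature.
#'
#' @param genome_id single string identifying the genome (strain name)
#' @param contigs named character vector of contig sequences (A/C/G/T/N);
#'   names are contig ids, unique and non-empty
#' @param genes data.frame with columns `gene_tag`, `contig_id`, `start`,
#'   `end` (1-based inclusive), `strand` (`+`/`-`), `nt_seq`, `aa_seq`,
#'   `annotation`
#' @param metadata free-form named list (genome size, GC fraction, CDS count)
#' @return object of class `annotated_genome`
#' @export
annotated_genome <- function(genome_id, contigs, genes = empty_gene_table(),
                             metadata = list()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            nzchar(genome_id))
  if (length(contigs) == 0L || is.null(names(contigs)) ||
      any(!nzchar(names(contigs))))
    stop("contigs must be a non-empty named character vector", call. = FALSE)
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig ids in genome ", genome_id, call. = FALSE)
  if (any(nchar(contigs) < 1L))
    stop("zero-length contig in genome ", genome_id, call. = FALSE)
  check_dna_alphabet(contigs, what = paste0("contig of ", genome_id))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_tag)) {
      dup <- genes$gene_tag[duplicated(genes$gene_tag)][1L]
      stop("duplicate gene_tag '", dup, "' in genome ", genome_id,
           call. = FALSE)
    }
    bad_contig <- !(genes$contig_id %in% names(contigs))
    if (any(bad_contig))
      stop("gene ", genes$gene_tag[bad_contig][1L],
           " refers to unknown contig ", genes$contig_id[bad_contig][1L],
           call. = FALSE)
    if (any(genes$start > genes$end))
      stop("gene with start > end in genome ", genome_id, call. = FALSE)
    clen <- nchar(contigs)[genes$contig_id]
    out <- genes$start < 1L | genes$end > clen
    if (any(out))
      stop("gene ", genes$gene_tag[out][1L],
           " lies outside its contig in genome ", genome_id, call. = FALSE)
    if (any(!genes$strand %in% c("+", "-")))
      stop("unknown strand symbol for gene ",
           genes$gene_tag[!genes$strand %in% c("+", "-")][1L], call. = FALSE)
  }
  structure(list(genome_id = genome_id,
                 contigs = contigs,
                 genes = genes,
                 metadata = metadata),
            class = "annotated_genome")
}

empty_gene_table <- function() {
  data.frame(gene_tag = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             nt_seq = character(), aa_seq = character(),
             annotation = character(), stringsAsFactors = FALSE)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d contig(s), %d gene(s), %.3f Mb\n",
              x$genome_id, length(x$contigs), nrow(x$genes),
              sum(nchar(x$contigs)) / 1e6))
  invisible(x)
}

# Vectorised bacterial-table translation with trailing stops removed.
translate_cds_many <- function(nt) {
  if (!length(nt)) return(character())
  out <- character(length(nt))
  ok <- nchar(nt) >= 3L
  if (any(ok)) {
    trimmed <- substr(nt[ok], 1L, 3L * (nchar(nt[ok]) %/% 3L))
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAStringSet(trimmed),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "X")))
    out[ok] <- sub("\\*$", "", aa)
  }
  out
}

gff3_unescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%26", "&", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Read an annotated genome from FASTA + GFF3
#'
#' CDS features are extracted with their nucleotide sequence (reverse
#' complemented on the minus strand) and bacterial-table translation
#' (trailing stop removed).  Ambiguity codes other than N are rejected so
#' that downstream k-mer and alignment stages can assume a 5-letter
#' alphabet.
#'
#' @param fasta_path genome FASTA (multi-record, wrapped or unwrapped)
#' @param gff_path GFF3 annotation; only features of type `CDS` are used
#' @param genome_id genome identifier; defaults to the FASTA base name
#' @param tag_attr GFF3 attribute carrying the unique gene tag
#'   (default `locus_tag`, with fallback to `ID` when absent)
#' @return an [annotated_genome()]
#' @export
read_genome <- function(fasta_path, gff_path,
                        genome_id = sub("\\.(fa|fna|fasta)$", "",
                                        basename(fasta_path)),
                        tag_attr = "locus_tag") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  freq <- Biostrings::alphabetFrequency(seqs)
  extra <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE])
  if (any(extra > 0))
    stop("contig ", names(seqs)[extra > 0][1L],
         " contains ambiguity codes other than N", call. = FALSE)
  contigs <- setNames(as.character(seqs), names(seqs))

  gff <- ape::read.gff(gff_path)
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  genes <- empty_gene_table()
  if (nrow(gff)) {
    attr_field <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"),
                                     attrs))
      val <- rep(NA_character_, length(attrs))
      hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)\\s*", key, "="),
                                                attrs))) > 0
      val[hit] <- sub(paste0("^.*", key, "="), "", m)
      gff3_unescape(val)
    }
    tags <- attr_field(gff$attributes, tag_attr)
    if (anyNA(tags)) {
      ids <- attr_field(gff$attributes, "ID")
      tags[is.na(tags)] <- ids[is.na(tags)]
    }
    if (anyNA(tags))
      stop("CDS feature without a '", tag_attr, "' (or ID) attribute in ",
           gff_path, call. = FALSE)
    if (anyDuplicated(tags))
      stop("duplicate gene tag '", tags[duplicated(tags)][1L], "' in ",
           gff_path, call. = FALSE)
    ann <- attr_field(gff$attributes, "product")
    ann[is.na(ann)] <- ""
    strand <- as.character(gff$strand)
    genes <- data.frame(gene_tag = tags,
                        contig_id = as.character(gff$seqid),
                        start = as.integer(gff$start),
                        end = as.integer(gff$end),
                        strand = strand,
                        nt_seq = NA_character_,
                        aa_seq = NA_character_,
                        annotation = ann,
                        stringsAsFactors = FALSE)
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand symbol for feature ",
           tags[!strand %in% c("+", "-")][1L], call. = FALSE)
    bad <- !(genes$contig_id %in% names(contigs))
    if (any(bad))
      stop("feature ", genes$gene_tag[bad][1L], " names unknown contig ",
           genes$contig_id[bad][1L], call. = FALSE)
    clen <- nchar(contigs)[genes$contig_id]
    out <- genes$start < 1L | genes$end > clen | genes$start > genes$end
    if (any(out))
      stop("feature ", genes$gene_tag[out][1L],
           " has coordinates outside its contig", call. = FALSE)
    nt <- substr(contigs[genes$contig_id], genes$start, genes$end)
    minus <- genes$strand == "-"
    nt[minus] <- revcomp(nt[minus])
    genes$nt_seq <- unname(nt)
    genes$aa_seq <- translate_cds_many(genes$nt_seq)
  }
  gc <- sum(Biostrings::letterFrequency(seqs, "GC")) / sum(nchar(contigs))
  annotated_genome(genome_id, contigs, genes,
                   metadata = list(size_bp = sum(nchar(contigs)),
                                   gc = unname(gc),
                                   n_cds = nrow(genes)))
}

#' Write an annotated genome as FASTA + GFF3
#'
#' Inverse of [read_genome()]: the FASTA carries the contigs and the GFF3
#' one CDS feature per gene with `ID`, `locus_tag` and `product` attributes.
#'
#' @param genome an [annotated_genome()]
#' @param fasta_path,gff_path output paths
#' @return invisibly, the genome
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  stopifnot(inherits(genome, "annotated_genome"))
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  g <- genome$genes
  lines <- "##gff-version 3"
  if (nrow(g)) {
    attrs <- sprintf("ID=%s;locus_tag=%s;product=%s",
                     gff3_escape(g$gene_tag), gff3_escape(g$gene_tag),
                     gff3_escape(g$annotation))
    lines <- c(lines,
               sprintf("%s\tstrainmark\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                       g$contig_id, g$start, g$end, g$strand, attrs))
  }
  writeLines(lines, gff_path)
  invisible(genome)
}

# Roary emits a variable set of per-family statistic columns between
# "Annotation" and the genome columns; they are recognised by name.
ROARY_STAT_COLUMNS <- c(
  "No. isolates", "No. sequences", "Avg sequences per isolate",
  "Genome Fragment", "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC",
  "Min group size nuc", "Max group size nuc", "Avg group size nuc")

#' Read a gene presence/absence table (Roary CSV dialect)
#'
#' Accepts the `gene_presence_absence.csv` layout: three fixed leading
#' columns (`Gene`, `Non-unique Gene name`, `Annotation`), an optional block
#' of per-family statistic columns recognised by name, then one column per
#' genome whose cells hold the member gene tags (empty = absent; several
#' tab-separated tags in one cell = paralogs, collapsed to a single
#' presence).
#'
#' @param path CSV file
#' @return a [presence_absence_matrix()]
#' @export
read_presence_absence_csv <- function(path) {
  nf <- count.fields(path, sep = ",", quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row ", bad, " in ", path, ": ", nf[bad],
         " fields where ", nf[1L], " expected", call. = FALSE)
  }
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 comment.char = "")
  lead <- tolower(gsub("[^a-z]", "", tolower(names(df)[1:3])))
  want <- c("gene", "nonuniquegenename", "annotation")
  if (ncol(df) < 4L || !identical(lead, want))
    stop("header must begin with Gene, Non-unique Gene name, Annotation",
         call. = FALSE)
  body <- df[, -(1:3), drop = FALSE]
  is_stat <- names(body) %in% ROARY_STAT_COLUMNS
  avg_len <- if ("Avg group size nuc" %in% names(body))
    suppressWarnings(as.numeric(body[["Avg group size nuc"]])) else NULL
  genome_cols <- body[, !is_stat, drop = FALSE]
  if (ncol(genome_cols) == 0L)
    stop("no genome columns found in ", path, call. = FALSE)
  genome_ids <- names(genome_cols)
  cluster_ids <- df[[1L]]
  if (anyDuplicated(cluster_ids))
    stop("duplicate family id '",
         cluster_ids[duplicated(cluster_ids)][1L], "' in ", path,
         call. = FALSE)
  incidence <- as.matrix(genome_cols) != ""
  dimnames(incidence) <- list(cluster_ids, genome_ids)
  clusters <- lapply(seq_along(cluster_ids), function(i) {
    cells <- as.character(genome_cols[i, ])
    keep <- nzchar(cells)
    tags <- strsplit(cells[keep], "[\t ]+")
    members <- data.frame(
      genome_id = rep(genome_ids[keep], lengths(tags)),
      gene_tag = unlist(tags, use.names = FALSE) %||% character(),
      stringsAsFactors = FALSE)
    gene_cluster(cluster_ids[i], members,
                 representative = if (nrow(members)) members$gene_tag[1L]
                 else NA_character_,
                 avg_nt_len = if (is.null(avg_len)) NA_real_ else avg_len[i],
                 gene_name = df[[2L]][i], annotation = df[[3L]][i])
  })
  presence_absence_matrix(genome_ids, clusters, incidence)
}

#' Write a presence/absence table in the Roary CSV dialect
#'
#' @param mat a [presence_absence_matrix()]
#' @param path output CSV
#' @return invisibly, `mat`
#' @export
write_presence_absence_csv <- function(mat, path) {
  stopifnot(inherits(mat, "presence_absence_matrix"))
  cells <- matrix("", nrow = length(mat$clusters),
                  ncol = length(mat$genome_ids),
                  dimnames = list(NULL, mat$genome_ids))
  for (i in seq_along(mat$clusters)) {
    cl <- mat$clusters[[i]]
    if (nrow(cl$members)) {
      tag_by_genome <- split(cl$members$gene_tag, cl$members$genome_id)
      cells[i, names(tag_by_genome)] <-
        vapply(tag_by_genome, paste, character(1), collapse = "\t")
    }
  }
  df <- data.frame(
    Gene = vapply(mat$clusters, `[[`, character(1), "cluster_id"),
    `Non-unique Gene name` = vapply(mat$clusters, function(cl)
      cl$gene_name %||% "", character(1)),
    Annotation = vapply(mat$clusters, function(cl)
      cl$annotation %||% "", character(1)),
    `Avg group size nuc` = vapply(mat$clusters, function(cl)
      cl$avg_nt_len %||% NA_real_, numeric(1)),
    check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cells, stringsAsFactors = FALSE,
                                check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(mat)
}

#' Write the marker report table
#'
#' One row per selected marker with the five column roles of the published
#' strain-specific gene tables: family id, non-unique gene name, annotation,
#' average family nucleotide length, and gene tag.  Rows are sorted by gene
#' tag.
#'
#' @param markers list of [marker_candidate()] objects (may be empty)
#' @param path output CSV
#' @return invisibly, the data.frame written
#' @export
write_marker_table <- function(markers, path) {
  df <- data.frame(
    Gene = vapply(markers, function(m) m$cluster_id %||% "", character(1)),
    `Non-Unique Gene Name` = vapply(markers, function(m)
      m$gene_name %||% "", character(1)),
    Annotation = vapply(markers, function(m)
      m$annotation %||% "", character(1)),
    `Avg Group Size Nuc` = vapply(markers, function(m)
      m$avg_nt_len %||% m$length_bp, numeric(1)),
    `Gene Tag` = vapply(markers, `[[`, character(1), "gene_tag"),
    check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df[["Gene Tag"]]), , drop = FALSE]
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write marker table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(df)
}
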