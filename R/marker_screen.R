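# Nucleotide-level specificity screening of candidate strain-unique genes.
# Mirrors the two-tier BLASTN screen of marker pipelines: first against all
# non-target genomes of the collection ("in-house"), then against an
# arbitrary local sequence database standing in for NR/NT.  The engine uses
# exact 11-mer seeds on both strands, ungapped X-drop extension and gapped
# local refinement with BLASTN-like scores (+2/-3, gap open 5, extend 2).

#' Hit definition and engine parameters for the nucleotide screen
#'
#' A subject is considered hit when a local alignment reaches `min_len`
#' columns at `min_id` identity, or when an exact match of at least
#' `exact_min` bp exists.  These cut-offs are package-level defaults (the
#' screening criterion of the original BLASTN workflow is not published) and
#' are recorded in every report.
#'
#' @param min_len minimum alignment length (bp) of an identity-based hit
#' @param min_id minimum identity fraction of an identity-based hit
#' @param exact_min exact-match length (bp) that constitutes a hit on its own
#' @param word_size exact seed length
#' @param match,mismatch,gap_open,gap_ext alignment scores
#' @param xdrop ungapped extension drop-off
#' @return list of class `screen_params`
#' @export
screen_params <- function(min_len = 60L, min_id = 0.80, exact_min = 25L,
                          word_size = 11L, match = 2L, mismatch = -3L,
                          gap_open = 5L, gap_ext = 2L, xdrop = 20L) {
  structure(list(min_len = as.integer(min_len), min_id = min_id,
                 exact_min = as.integer(exact_min),
                 word_size = as.integer(word_size),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext),
                 xdrop = as.integer(xdrop)),
            class = "screen_params")
}

#' Construct a marker candidate
#'
#' A strain-unique gene with its three-tier screening status: protein-level
#' uniqueness (from the pangenome), nucleotide uniqueness within the
#' collection, and no-hit status against an external database.
#'
#' @param strain_id genome carrying the candidate
#' @param gene_tag gene tag
#' @param nt_seq nucleotide sequence
#' @param cluster_id,gene_name,annotation,avg_nt_len optional family fields
#' @param protein_unique initial flag for the clustering tier
#' @return object of class `marker_candidate`
#' @export
marker_candidate <- function(strain_id, gene_tag, nt_seq,
                             cluster_id = NA_character_, gene_name = "",
                             annotation = "", avg_nt_len = NA_real_,
                             protein_unique = "pass") {
  check_dna_alphabet(nt_seq, what = paste0("candidate ", gene_tag))
  structure(list(strain_id = strain_id, gene_tag = gene_tag,
                 nt_seq = toupper(nt_seq), length_bp = nchar(nt_seq),
                 cluster_id = cluster_id, gene_name = gene_name,
                 annotation = annotation, avg_nt_len = avg_nt_len,
                 status = list(protein_unique = protein_unique,
                               nt_unique_inhouse = "not_run",
                               nt_no_hit_external = "not_run"),
                 hits = empty_hit_table()),
            class = "marker_candidate")
}

empty_hit_table <- function() {
  data.frame(tier = character(), subject_db = character(),
             subject = character(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), strand = character(),
             length = integer(), identity = numeric(), score = numeric(),
             exact_run = integer(), stringsAsFactors = FALSE)
}

#' @export
print.marker_candidate <- function(x, ...) {
  st <- x$status
  cat(sprintf("<marker_candidate> %s (%s, %d bp) protein:%s inhouse:%s external:%s; %d hit(s)\n",
              x$gene_tag, x$strain_id, x$length_bp, st$protein_unique,
              st$nt_unique_inhouse, st$nt_no_hit_external, nrow(x$hits)))
  invisible(x)
}

#' Candidates from the strain-unique families of a target genome
#'
#' Convenience bridge from [unique_genes()] to the nucleotide screen: one
#' candidate per unique family, using the target genome's member gene.
#'
#' @param genomes list of [annotated_genome()] objects
#' @param matrix a [presence_absence_matrix()]
#' @param target genome id
#' @return list of [marker_candidate()] objects
#' @export
candidates_for <- function(genomes, matrix, target) {
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")
  g <- genomes[[target]]
  if (is.null(g)) stop("unknown genome '", target, "'", call. = FALSE)
  lapply(unique_genes(matrix, target), function(cl) {
    tag <- cl$members$gene_tag[cl$members$genome_id == target][1L]
    row <- g$genes[match(tag, g$genes$gene_tag), ]
    marker_candidate(target, tag, row$nt_seq, cluster_id = cl$cluster_id,
                     gene_name = cl$gene_name %||% "",
                     annotation = row$annotation %||% "",
                     avg_nt_len = cl$avg_nt_len)
  })
}

run_screen <- function(candidate, subject_seqs, subject_names, db_labels,
                       tier, params) {
  if (candidate$length_bp < params$word_size)
    stop("candidate ", candidate$gene_tag, " shorter than the seed length (",
         params$word_size, " bp)", call. = FALSE)
  hits <- screen_query_cpp(candidate$nt_seq, subject_seqs,
                           word_size = params$word_size,
                           match = params$match, mismatch = params$mismatch,
                           gap_open = params$gap_open,
                           gap_ext = params$gap_ext, xdrop = params$xdrop,
                           min_len = params$min_len, min_id = params$min_id,
                           exact_min = params$exact_min)
  if (nrow(hits)) {
    hits <- data.frame(tier = tier,
                       subject_db = db_labels[hits$subject],
                       subject = subject_names[hits$subject],
                       hits[, c("qstart", "qend", "sstart", "send", "strand",
                                "length", "identity", "score", "exact_run")],
                       stringsAsFactors = FALSE)
  } else hits <- empty_hit_table()
  hits
}

#' Screen a candidate against all non-target genomes of the collection
#'
#' The candidate passes (`nt_unique_inhouse = "pass"`) iff the seeded local
#' search finds zero hits under the hit definition in `params` over every
#' contig of every non-target genome, both strands.
#'
#' @param candidate a [marker_candidate()]
#' @param genomes list of [annotated_genome()]; the candidate's own genome
#'   is excluded automatically
#' @param params a [screen_params()]
#' @return the candidate with `nt_unique_inhouse` set and hits recorded
#' @export
screen_inhouse <- function(candidate, genomes, params = screen_params()) {
  stopifnot(inherits(candidate, "marker_candidate"))
  others <- Filter(function(g) g$genome_id != candidate$strain_id, genomes)
  subject_seqs <- character()
  subject_names <- character()
  db_labels <- character()
  for (g in others) {
    subject_seqs <- c(subject_seqs, unname(g$contigs))
    subject_names <- c(subject_names, names(g$contigs))
    db_labels <- c(db_labels, rep(g$genome_id, length(g$contigs)))
  }
  hits <- if (length(subject_seqs))
    run_screen(candidate, subject_seqs, subject_names, db_labels,
               "inhouse", params)
  else empty_hit_table()
  candidate$hits <- rbind(candidate$hits[candidate$hits$tier != "inhouse", ],
                          hits)
  candidate$status$nt_unique_inhouse <- if (nrow(hits)) "fail" else "pass"
  candidate
}

#' Screen a candidate against an external sequence database
#'
#' Same engine and hit definition as [screen_inhouse()], applied to a local
#' FASTA database standing in for a remote nucleotide collection.  An empty
#' database cannot certify anything: the flag is left `not_run` with a
#' warning.
#'
#' @param candidate a [marker_candidate()]
#' @param db_fasta path to the database FASTA
#' @param params a [screen_params()]
#' @return the candidate with `nt_no_hit_external` set and hits recorded
#' @export
screen_external <- function(candidate, db_fasta, params = screen_params()) {
  stopifnot(inherits(candidate, "marker_candidate"))
  db <- Biostrings::readDNAStringSet(db_fasta)
  if (length(db) == 0L) {
    warning("external database ", db_fasta,
            " is empty; flag left as not_run", call. = FALSE)
    candidate$status$nt_no_hit_external <- "not_run"
    return(candidate)
  }
  nm <- sub("\\s.*$", "", names(db))
  hits <- run_screen(candidate, as.character(db), nm,
                     rep(basename(db_fasta), length(db)), "external",
                     params)
  candidate$hits <- rbind(candidate$hits[candidate$hits$tier != "external", ],
                          hits)
  candidate$status$nt_no_hit_external <- if (nrow(hits)) "fail" else "pass"
  candidate
}

#' Select final markers from screened candidates
#'
#' Keeps candidates whose every executed screening tier passed and whose
#' length reaches `min_len` (room for an amplicon plus primer flanks),
#' sorted by length descending.
#'
#' @param candidates list of [marker_candidate()] objects
#' @param min_len minimum marker length in bp
#' @return filtered, sorted list
#' @export
select_markers <- function(candidates, min_len = 300L) {
  keep <- Filter(function(cd) {
    flags <- unlist(cd$status)
    all(flags[flags != "not_run"] == "pass") &&
      cd$status$nt_unique_inhouse == "pass" &&
      cd$length_bp >= min_len
  }, candidates)
  keep[order(-vapply(keep, `[[`, numeric(1), "length_bp"))]
}

#' Write a screening report as TSV
#'
#' @param candidates list of screened [marker_candidate()] objects
#' @param path output TSV
#' @export
write_screen_report <- function(candidates, path) {
  rows <- lapply(candidates, function(cd) {
    base <- data.frame(candidate = cd$gene_tag, strain = cd$strain_id,
                       length_bp = cd$length_bp,
                       protein_unique = cd$status$protein_unique,
                       nt_unique_inhouse = cd$status$nt_unique_inhouse,
                       nt_no_hit_external = cd$status$nt_no_hit_external,
                       stringsAsFactors = FALSE)
    hits <- if (nrow(cd$hits)) cd$hits else {
      h <- empty_hit_table()[NA_integer_, , drop = FALSE]
      rownames(h) <- NULL
      h
    }
    cbind(base[rep(1L, nrow(hits)), , drop = FALSE], hits,
          row.names = NULL)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
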