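# qPCR primer design on a selected marker: nearest-neighbor melting
# temperatures, exhaustive window enumeration under per-primer and per-pair
# constraints, in-silico PCR across whole genome collections, and
# specificity certification (exactly one target amplicon, zero elsewhere).

# Unified nearest-neighbor dinucleotide parameters (SantaLucia 1998):
# enthalpy in kcal/mol, entropy in cal/(mol K).  Each 5'->3' dinucleotide
# maps onto itself or its reverse complement.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(AT = 2.3, GC = 0.1)   # per-terminal initiation
NN_INIT_DS <- c(AT = 4.1, GC = -2.8)

#' Oligonucleotide melting temperature (nearest-neighbor model)
#'
#' Duplex melting temperature from the unified dinucleotide
#' enthalpy/entropy parameter set with terminal initiation terms, an
#' entropic monovalent-salt correction of 0.368 (N-1) ln[Na+] and the
#' two-state formula Tm = 1000 dH / (dS + R ln(C/4)) - 273.15, where C is
#' the total primer concentration (non-self-complementary duplex, both
#' strands equimolar).
#'
#' @param seq character vector of primer sequences (A/C/G/T only)
#' @param monovalent_mM monovalent cation concentration in mM
#' @param primer_nM total primer concentration in nM
#' @return numeric vector of melting temperatures in degrees Celsius
#' @export
melting_temperature <- function(seq, monovalent_mM = 50, primer_nM = 400) {
  seq <- toupper(seq)
  if (any(nchar(seq) < 8L))
    stop("primers must be at least 8 nt for the nearest-neighbor model",
         call. = FALSE)
  if (any(!grepl("^[ACGT]+$", seq)))
    stop("melting_temperature requires an unambiguous A/C/G/T sequence",
         call. = FALSE)
  R <- 1.987  # cal/(mol K)
  ct <- primer_nM * 1e-9
  vapply(seq, function(s) {
    n <- nchar(s)
    di <- substring(s, 1:(n - 1L), 2:n)
    dh <- sum(NN_DH[di])
    ds <- sum(NN_DS[di])
    for (term in c(substr(s, 1L, 1L), substr(s, n, n))) {
      key <- if (term %in% c("A", "T")) "AT" else "GC"
      dh <- dh + NN_INIT_DH[[key]]
      ds <- ds + NN_INIT_DS[[key]]
    }
    ds <- ds + 0.368 * (n - 1L) * log(monovalent_mM / 1000)
    unname(1000 * dh / (ds + R * log(ct / 4)) - 273.15)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Validate a primer sequence
#'
#' Checks the alphabet (strict A/C/G/T) and returns basic descriptors.
#'
#' @param seq single primer sequence, 5'->3'
#' @return list with `seq`, `length`, `gc` (fraction) and `tm`
#' @export
validate_primer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq))
    stop("primer contains non-A/C/G/T characters", call. = FALSE)
  list(seq = seq, length = nchar(seq), gc = gc_fraction(seq),
       tm = if (nchar(seq) >= 8L) melting_temperature(seq) else NA_real_)
}

gc_fraction <- function(seq) {
  vapply(strsplit(toupper(seq), "", fixed = TRUE), function(ch)
    mean(ch %in% c("G", "C")), numeric(1))
}

max_homopolymer <- function(seq) {
  vapply(seq, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, numeric(1), USE.NAMES = FALSE)
}

# Longest common substring length between two short strings (DP).
lcs_run <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- 0L
  prev <- integer(length(cb) + 1L)
  for (i in seq_along(ca)) {
    cur <- integer(length(cb) + 1L)
    for (j in seq_along(cb)) {
      if (ca[i] == cb[j]) {
        cur[j + 1L] <- prev[j] + 1L
        if (cur[j + 1L] > best) best <- cur[j + 1L]
      }
    }
    prev <- cur
  }
  best
}

# Longest antiparallel complementary duplex between two primers
# (= longest common substring of a and revcomp(b)).
dimer_run <- function(a, b) lcs_run(a, revcomp(b))

# Longest complementary run anchored at the 3' terminal base of `a`
# against any site of `b` (self-dimer when b = a).
three_prime_run <- function(a, b) {
  rb <- revcomp(b)
  n <- nchar(a)
  best <- 0L
  for (L in seq_len(min(n, nchar(rb)))) {
    suf <- substr(a, n - L + 1L, n)
    if (grepl(suf, rb, fixed = TRUE)) best <- L else break
  }
  best
}

# Longest self-complementary stem with a loop of at least `min_loop` bases.
hairpin_run <- function(a, min_loop = 3L) {
  ch <- strsplit(a, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")[ch]
  n <- length(ch)
  best <- 0L
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq(n, i + 1L, by = -1L)) {
      r <- 0L
      while (i + r <= n && j - r >= 1L && j - r > i + r &&
             ch[i + r] == comp[j - r]) r <- r + 1L
      if (r > best && (j - (i + 2L * r - 1L)) >= min_loop - 1L) {
        stem_end <- i + r - 1L
        loop <- (j - r + 1L) - stem_end - 1L
        if (loop >= min_loop) best <- r
      }
    }
  }
  best
}

#' Primer-pair design constraints
#'
#' Defaults bracket typical qPCR designs: 17-24 nt primers, 100-250 bp
#' products, Tm 57-63 degrees C with at most 3 degrees between the two
#' primers, GC 40-60%, homopolymers of at most 4, and short
#' complementarity runs.
#'
#' @param primer_len integer range of primer lengths (nt)
#' @param product_len integer range of product lengths (bp)
#' @param tm_range allowed Tm interval (degrees C)
#' @param gc_range allowed GC fraction interval
#' @param max_homopolymer longest allowed single-base run
#' @param max_3p_self longest allowed 3'-anchored self-complementary run
#' @param max_dtm largest allowed |Tm(fwd) - Tm(rev)|
#' @return list of class `primer_constraints`
#' @export
primer_constraints <- function(primer_len = c(17L, 24L),
                               product_len = c(100L, 250L),
                               tm_range = c(57, 63), gc_range = c(0.40, 0.60),
                               max_homopolymer = 4L, max_3p_self = 4L,
                               max_dtm = 3) {
  structure(list(primer_len = as.integer(primer_len),
                 product_len = as.integer(product_len),
                 tm_range = tm_range, gc_range = gc_range,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_3p_self = as.integer(max_3p_self), max_dtm = max_dtm),
            class = "primer_constraints")
}

#' Enumerate scored primer pairs on a marker
#'
#' All primer windows satisfying the per-primer constraints are paired when
#' the product length and Tm difference constraints hold; pairs with a long
#' 3'-anchored cross-complementary run are rejected outright.  Each
#' surviving pair is scored by a penalty (sum of weighted deviations:
#' |Tm - 60| per primer, GC deviation from 0.5, hairpin and 3' self-dimer
#' runs, |dTm|); only the ordering the penalty induces is meaningful.  The
#' result is sorted ascending by penalty with deterministic tie-breaks
#' (fwd_start, product_len, rev_start).
#'
#' @param marker a [marker_candidate()] or a plain nucleotide string
#' @param constraints a [primer_constraints()]
#' @param monovalent_mM,primer_nM Tm model conditions
#' @return data.frame with one row per pair: `fwd_seq`, `rev_seq`,
#'   `fwd_start`, `rev_start` (0-based positions on the marker),
#'   `product_len`, `fwd_tm`, `rev_tm`, `fwd_gc`, `rev_gc`, `penalty`.
#'   When no pair satisfies the constraints an empty data.frame is returned
#'   with attribute `rejections`, a named count of which constraint removed
#'   most windows.
#' @export
enumerate_pairs <- function(marker, constraints = primer_constraints(),
                            monovalent_mM = 50, primer_nM = 400) {
  seq <- if (inherits(marker, "marker_candidate")) marker$nt_seq
         else toupper(marker)
  n <- nchar(seq)
  if (n < constraints$product_len[1L])
    stop("marker (", n, " bp) shorter than the minimum product length (",
         constraints$product_len[1L], " bp)", call. = FALSE)

  rej <- c(alphabet = 0L, gc = 0L, homopolymer = 0L, tm = 0L,
           self3p = 0L, hairpin = 0L)
  wins <- list()
  k <- 0L
  for (len in constraints$primer_len[1L]:constraints$primer_len[2L]) {
    if (len > n) next
    starts <- 0:(n - len)                    # 0-based
    ws <- substring(seq, starts + 1L, starts + len)
    ok <- grepl("^[ACGT]+$", ws)
    rej["alphabet"] <- rej["alphabet"] + sum(!ok)
    gc <- ifelse(ok, gc_fraction(ws), NA)
    gok <- ok & gc >= constraints$gc_range[1L] & gc <= constraints$gc_range[2L]
    rej["gc"] <- rej["gc"] + sum(ok & !gok, na.rm = TRUE)
    hok <- gok
    hok[gok] <- max_homopolymer(ws[gok]) <= constraints$max_homopolymer
    rej["homopolymer"] <- rej["homopolymer"] + sum(gok & !hok)
    if (!any(hok)) next
    tm <- rep(NA_real_, length(ws))
    tm[hok] <- melting_temperature(ws[hok], monovalent_mM, primer_nM)
    tok <- hok & tm >= constraints$tm_range[1L] & tm <= constraints$tm_range[2L]
    rej["tm"] <- rej["tm"] + sum(hok & !tok, na.rm = TRUE)
    if (!any(tok)) next
    for (i in which(tok)) {
      k <- k + 1L
      wins[[k]] <- list(start = starts[i], len = len, seq = ws[i],
                        gc = gc[i], tm = tm[i])
    }
  }
  empty <- data.frame(fwd_seq = character(), rev_seq = character(),
                      fwd_start = integer(), rev_start = integer(),
                      product_len = integer(), fwd_tm = numeric(),
                      rev_tm = numeric(), fwd_gc = numeric(),
                      rev_gc = numeric(), penalty = numeric(),
                      stringsAsFactors = FALSE)
  if (!k) {
    attr(empty, "rejections") <- rej
    message("no primer window satisfied the per-primer constraints; ",
            "rejection counts: ",
            paste(names(rej), rej, sep = "=", collapse = ", "))
    return(empty)
  }

  # 3'-anchored self-complementarity and hairpin gates, per surviving window
  keep <- logical(k)
  for (i in seq_len(k)) {
    w <- wins[[i]]
    s3_f <- three_prime_run(w$seq, w$seq)
    hp <- hairpin_run(w$seq)
    if (s3_f > constraints$max_3p_self) { rej["self3p"] <- rej["self3p"] + 1L
    } else if (hp > constraints$max_3p_self + 2L) {
      rej["hairpin"] <- rej["hairpin"] + 1L
    } else keep[i] <- TRUE
    wins[[i]]$self3p <- s3_f
    wins[[i]]$hairpin <- hp
  }
  wins <- wins[keep]
  if (!length(wins)) {
    attr(empty, "rejections") <- rej
    message("no primer window survived the complementarity gates; ",
            "rejection counts: ",
            paste(names(rej), rej, sep = "=", collapse = ", "))
    return(empty)
  }

  starts <- vapply(wins, `[[`, numeric(1), "start")
  lens <- vapply(wins, `[[`, numeric(1), "len")
  ends <- starts + lens                       # 0-based exclusive
  tms <- vapply(wins, `[[`, numeric(1), "tm")
  gcs <- vapply(wins, `[[`, numeric(1), "gc")
  seqs_w <- vapply(wins, `[[`, character(1), "seq")
  hps <- vapply(wins, `[[`, numeric(1), "hairpin")
  s3s <- vapply(wins, `[[`, numeric(1), "self3p")
  rcs <- revcomp(seqs_w)

  # all (fwd, rev) window index pairs within product and dTm bounds
  pl <- outer(-starts, ends, `+`)             # product length [fwd, rev]
  ok <- pl >= constraints$product_len[1L] & pl <= constraints$product_len[2L]
  ok <- ok & abs(outer(tms, tms, `-`)) <= constraints$max_dtm
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) {
    attr(empty, "rejections") <- rej
    message("no window pair satisfied the product/Tm-difference ",
            "constraints; rejection counts: ",
            paste(names(rej), rej, sep = "=", collapse = ", "))
    return(empty)
  }
  fi <- idx[, 1L]; ri <- idx[, 2L]

  # cross-dimer gate: a 3'-anchored complementary run longer than
  # max_3p_self + 2 between the two primers rejects the pair.  The run is
  # anchored at a 3' end, so the test reduces to one fixed-string search
  # per direction (the reverse primer's complement is the marker window
  # itself).
  gate_len <- constraints$max_3p_self + 3L
  fwd_suf <- substr(seqs_w, pmax(1L, lens - gate_len + 1L), lens)
  rev_suf <- substr(rcs, pmax(1L, lens - gate_len + 1L), lens)
  bad <- mapply(function(f, r) {
    grepl(fwd_suf[f], seqs_w[r], fixed = TRUE) ||
      grepl(rev_suf[r], rcs[f], fixed = TRUE)
  }, fi, ri)
  fi <- fi[!bad]; ri <- ri[!bad]
  if (!length(fi)) {
    attr(empty, "rejections") <- rej
    message("all window pairs rejected by the cross-dimer gate; ",
            "rejection counts: ",
            paste(names(rej), rej, sep = "=", collapse = ", "))
    return(empty)
  }

  dtm <- abs(tms[fi] - tms[ri])
  penalty <- abs(tms[fi] - 60) + abs(tms[ri] - 60) +
    10 * (abs(gcs[fi] - 0.5) + abs(gcs[ri] - 0.5)) +
    0.5 * (hps[fi] + hps[ri] + s3s[fi] + s3s[ri]) + dtm
  out <- data.frame(
    fwd_seq = seqs_w[fi], rev_seq = rcs[ri],
    fwd_start = as.integer(starts[fi]), rev_start = as.integer(starts[ri]),
    product_len = as.integer(ends[ri] - starts[fi]),
    fwd_tm = tms[fi], rev_tm = tms[ri], fwd_gc = gcs[fi], rev_gc = gcs[ri],
    penalty = penalty, stringsAsFactors = FALSE)
  out <- out[order(out$penalty, out$fwd_start, out$product_len,
                   out$rev_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Binding sites of one primer on one contig: plus orientation (primer
# sequence matches the template top strand and extends rightward) and minus
# orientation (reverse complement matches; primer extends leftward).
primer_sites <- function(primer, contig_seq, max_mismatch, three_prime_exact) {
  subj <- Biostrings::DNAString(contig_seq)
  plen <- nchar(primer)
  e <- min(three_prime_exact, plen)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = max_mismatch)
    if (length(m) == 0L) next
    st <- IRanges::start(m)
    keep <- logical(length(st))
    mm <- integer(length(st))
    for (i in seq_along(st)) {
      tpl <- substr(contig_seq, st[i], st[i] + plen - 1L)
      pc <- strsplit(pat, "", fixed = TRUE)[[1]]
      tc <- strsplit(tpl, "", fixed = TRUE)[[1]]
      mm[i] <- sum(pc != tc)
      exact_ok <- if (strand == "+")
        all(pc[(plen - e + 1L):plen] == tc[(plen - e + 1L):plen])
      else all(pc[1:e] == tc[1:e])
      keep[i] <- exact_ok && mm[i] <= max_mismatch
    }
    if (any(keep))
      out[[strand]] <- data.frame(start = st[keep],
                                  end = st[keep] + plen - 1L,
                                  strand = strand,
                                  mismatches = mm[keep],
                                  stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Predict PCR amplicons of a primer pair across genomes
#'
#' A primer binds where its sequence matches the template (either strand)
#' with at most `max_mismatch` mismatches and its `three_prime_exact`
#' 3'-terminal bases exact.  An amplicon is any convergent, opposed pair of
#' binding sites (one primer on each strand, the minus-strand site
#' downstream) spanning at most `max_product` bases.  Both pairings
#' (forward primer on the top strand, or the reverse primer on the top
#' strand) are reported, so markers integrated in either orientation are
#' found.
#'
#' @param pair one row of [enumerate_pairs()] output, or any list with
#'   `fwd_seq` and `rev_seq`
#' @param genomes list of [annotated_genome()] objects
#' @param max_mismatch per-primer mismatch tolerance
#' @param three_prime_exact number of 3'-terminal bases required exact
#' @param max_product largest product length considered amplifiable (bp)
#' @return data.frame of amplicon hits: genome, contig, 1-based site
#'   coordinates and strands per primer, mismatch counts, `product_len`
#' @export
in_silico_pcr <- function(pair, genomes, max_mismatch = 2L,
                          three_prime_exact = 3L, max_product = 2000L) {
  fwd <- toupper(as.character(pair$fwd_seq)[1L])
  rev <- toupper(as.character(pair$rev_seq)[1L])
  check_dna_alphabet(c(fwd, rev), what = "primer", allow_n = FALSE)
  hits <- list()
  h <- 0L
  for (g in genomes) {
    for (ct in names(g$contigs)) {
      cs <- g$contigs[[ct]]
      sf <- primer_sites(fwd, cs, max_mismatch, three_prime_exact)
      sr <- primer_sites(rev, cs, max_mismatch, three_prime_exact)
      if (is.null(sf) || is.null(sr)) next
      combos <- list(c("+", "-"), c("-", "+"))
      for (cb in combos) {
        a <- sf[sf$strand == cb[1L], , drop = FALSE]
        b <- sr[sr$strand == cb[2L], , drop = FALSE]
        if (!nrow(a) || !nrow(b)) next
        for (ia in seq_len(nrow(a))) for (ib in seq_len(nrow(b))) {
          # upstream site must be the plus-strand one
          up <- if (cb[1L] == "+") a[ia, ] else b[ib, ]
          dn <- if (cb[1L] == "+") b[ib, ] else a[ia, ]
          if (dn$strand != "-" || up$strand != "+") next
          if (dn$start < up$start) next
          prod <- dn$end - up$start + 1L
          if (prod > max_product || prod < max(nchar(fwd), nchar(rev)))
            next
          h <- h + 1L
          hits[[h]] <- data.frame(
            genome_id = g$genome_id, contig = ct,
            fwd_start = a[ia, "start"], fwd_strand = a[ia, "strand"],
            fwd_mismatches = a[ia, "mismatches"],
            rev_start = b[ib, "start"], rev_strand = b[ib, "strand"],
            rev_mismatches = b[ib, "mismatches"],
            product_len = prod, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!h)
    return(data.frame(genome_id = character(), contig = character(),
                      fwd_start = integer(), fwd_strand = character(),
                      fwd_mismatches = integer(), rev_start = integer(),
                      rev_strand = character(), rev_mismatches = integer(),
                      product_len = integer(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Certify strain specificity of a primer pair
#'
#' Pass iff in-silico PCR yields exactly one amplicon, located in the
#' target genome, with the designed product length, and no amplicon in any
#' other genome.
#'
#' @param pair one row of [enumerate_pairs()] output (needs `product_len`)
#' @param target target genome id
#' @param genomes list of [annotated_genome()] objects including the target
#' @param ... passed to [in_silico_pcr()]
#' @return list with `pass` (logical), `reason`, and the amplicon table
#' @export
certify_specificity <- function(pair, target, genomes, ...) {
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  if (!target %in% ids)
    stop("target '", target, "' not among the genomes", call. = FALSE)
  amp <- in_silico_pcr(pair, genomes, ...)
  off <- amp[amp$genome_id != target, , drop = FALSE]
  on <- amp[amp$genome_id == target, , drop = FALSE]
  designed <- as.integer(pair$product_len)[1L]
  pass <- nrow(off) == 0L && nrow(on) == 1L &&
    (is.na(designed) || on$product_len[1L] == designed)
  reason <- if (pass) "specific" else if (nrow(off))
    sprintf("%d off-target amplicon(s)", nrow(off)) else if (nrow(on) == 0L)
    "no target amplicon" else if (nrow(on) > 1L)
    sprintf("%d target amplicons", nrow(on)) else
    sprintf("target product %d bp differs from designed %d bp",
            on$product_len[1L], designed)
  list(pass = pass, reason = reason, amplicons = amp)
}

#' Design and certify primers for a marker
#'
#' Walks the enumerated pairs in penalty order and returns the first pair
#' certified strain-specific across the collection.
#'
#' @param marker a [marker_candidate()]
#' @param genomes list of [annotated_genome()] objects
#' @param constraints a [primer_constraints()]
#' @param max_tried number of top-ranked pairs to certify before giving up
#' @param ... passed to [in_silico_pcr()]
#' @return list with `pair` (one-row data.frame or NULL), `certification`,
#'   and `n_tried`
#' @export
design_primers <- function(marker, genomes,
                           constraints = primer_constraints(),
                           max_tried = 25L, ...) {
  pairs <- enumerate_pairs(marker, constraints)
  n_try <- min(nrow(pairs), max_tried)
  for (i in seq_len(n_try)) {
    cert <- certify_specificity(pairs[i, ], marker$strain_id, genomes, ...)
    if (cert$pass)
      return(list(pair = pairs[i, ], certification = cert, n_tried = i))
  }
  list(pair = NULL, certification = NULL, n_tried = n_try)
}

#' Write a primer report TSV
#'
#' One row per strain/pair mirroring the published primer table layout
#' (strain, F/R sequence 5'-3', primer length, product length) plus the
#' thermodynamic columns; the published "Primer Score" has no public
#' definition, so the package's own penalty is reported under `penalty`.
#'
#' @param designs named list (by strain) of [design_primers()] results
#' @param path output TSV
#' @export
write_primer_report <- function(designs, path) {
  rows <- lapply(names(designs), function(strain) {
    d <- designs[[strain]]
    if (is.null(d$pair)) return(NULL)
    p <- d$pair
    data.frame(strain = strain, fwd_seq = p$fwd_seq, rev_seq = p$rev_seq,
               fwd_len = nchar(p$fwd_seq), rev_len = nchar(p$rev_seq),
               product_len = p$product_len,
               fwd_tm = round(p$fwd_tm, 2), rev_tm = round(p$rev_tm, 2),
               fwd_gc = round(p$fwd_gc, 3), rev_gc = round(p$rev_gc, 3),
               penalty = round(p$penalty, 3), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
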