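# carbohydrate-response-element (ChoRE) detection: consensus-to-PWM
# construction and scanning of upstream regions on both strands.

.DNA_BASES <- c("A", "C", "G", "T")

#' ChoRE consensus motifs
#'
#' The two carbohydrate-response-element consensus motifs mediating
#' glucose-induced transcription: ChoRE-a `CACGAG(N)5CACGAG` and ChoRE-b
#' `CACACC(N)5CACGCG`.  Both are 17 bp with 12 informative (non-N)
#' positions.
#'
#' @return Named list of consensus pattern strings.
#' @examples
#' choreMotifs()
#' @export
choreMotifs <- function() {
  list(chore_a = "CACGAGNNNNNCACGAG",
       chore_b = "CACACCNNNNNCACGCG")
}

#' Position weight matrix from a degenerate consensus
#'
#' Builds a 4 x L weight matrix from a consensus over `{A,C,G,T,N}`:
#' informative positions put unit weight on the consensus base and zero
#' elsewhere; `N` positions are all-zero columns and never affect the score.
#' The maximum achievable score therefore equals the number of informative
#' positions, and a window's relative score is its fraction of matching
#' informative positions.
#'
#' @param pattern consensus string (e.g. an entry of [choreMotifs()]).
#' @param name optional motif name stored on the matrix.
#' @return Numeric matrix with rows `A`,`C`,`G`,`T` and attributes
#'   `n_informative` and `name`.
#' @export
pwmFromConsensus <- function(pattern, name = NULL) {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) >= 1)
  letters_ <- strsplit(toupper(pattern), "")[[1]]
  bad <- !(letters_ %in% c(.DNA_BASES, "N"))
  if (any(bad))
    .stopf("consensus contains invalid character '%s' at position %d",
           letters_[which(bad)[1]], which(bad)[1])
  pwm <- matrix(0, 4, length(letters_),
                dimnames = list(.DNA_BASES, NULL))
  inf_pos <- which(letters_ != "N")
  pwm[cbind(match(letters_[inf_pos], .DNA_BASES), inf_pos)] <- 1
  attr(pwm, "n_informative") <- length(inf_pos)
  attr(pwm, "name") <- if (is.null(name)) pattern else name
  pwm
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Scan a sequence with a consensus PWM
#'
#' Slides the PWM over every window of the sequence (and, by default, its
#' reverse complement) and reports windows whose relative score — matching
#' informative positions divided by the number of informative positions —
#' reaches `min_score`.  With the 12-informative-position ChoRE matrices a
#' `min_score` of 0.90 admits at most one informative mismatch (11/12 ≈
#' 0.917).  Overlapping hits are all reported; letters at `N` positions never
#' affect the score.  Reverse-strand hits are reported at forward-strand
#' coordinates with the forward-strand letters.
#'
#' @param seq character string or [Biostrings::DNAString] over `{A,C,G,T,N}`.
#' @param pwm matrix from [pwmFromConsensus()].
#' @param min_score minimum relative score in \\[0, 1\\] (default 0.90).
#' @param both_strands also scan the reverse complement (default `TRUE`).
#' @return `data.frame` with `start`, `end` (1-based inclusive within `seq`),
#'   `strand`, `score`, `match` (forward-strand letters) and `motif`; zero
#'   rows when the sequence is shorter than the motif or nothing passes.
#' @examples
#' pwm <- pwmFromConsensus(choreMotifs()$chore_b, "chore_b")
#' scanSequence("TTCACACCAAAAACACGCGTT", pwm)
#' @export
scanSequence <- function(seq, pwm, min_score = 0.90, both_strands = TRUE) {
  seq <- toupper(as.character(seq))
  L <- ncol(pwm)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      match = character(), motif = character())
  if (n < L) return(empty)
  hits_fwd <- .scanOneStrand(seq, pwm, min_score)
  out <- if (nrow(hits_fwd)) cbind(hits_fwd, strand = "+") else NULL
  if (both_strands) {
    rc <- .revcomp(seq)
    hits_rev <- .scanOneStrand(rc, pwm, min_score)
    if (nrow(hits_rev)) {
      mapped <- data.frame(start = n - hits_rev$end + 1L,
                           end = n - hits_rev$start + 1L,
                           score = hits_rev$score)
      mapped <- cbind(mapped, strand = "-")
      out <- rbind(out, mapped)
    }
  }
  if (is.null(out)) return(empty)
  out$match <- substring(seq, out$start, out$end)
  out$motif <- attr(pwm, "name")
  out <- out[order(out$start, out$strand), c("start", "end", "strand",
                                             "score", "match", "motif")]
  rownames(out) <- NULL
  out
}

.scanOneStrand <- function(seq, pwm, min_score) {
  L <- ncol(pwm)
  n <- nchar(seq)
  idx <- match(strsplit(seq, "")[[1]], .DNA_BASES)   # NA for N/other: mismatch
  cons <- apply(pwm, 2, function(col) if (any(col == 1)) which(col == 1) else NA)
  n_inf <- attr(pwm, "n_informative")
  n_win <- n - L + 1L
  matches <- integer(n_win)
  for (j in which(!is.na(cons))) {
    hit <- idx[seq_len(n_win) + j - 1L] == cons[j]
    hit[is.na(hit)] <- FALSE
    matches <- matches + hit
  }
  score <- matches / n_inf
  pass <- which(score >= min_score)
  data.frame(start = pass, end = pass + L - 1L, score = score[pass])
}

#' Extract the upstream region of a gene
#'
#' Returns the `length`-bp region upstream of the transcription start site in
#' promoter orientation: for a `+`-strand gene the genomic window
#' `[tss - length, tss - 1]` as-is; for a `-`-strand gene the reverse
#' complement of `[tss + 1, tss + length]`.  Regions are truncated at
#' chromosome ends with a warning.
#'
#' @param gene one gene: a single-row [GenomicRanges::GRanges] with `tss_bp`
#'   and strand (as from [readGeneModels()]), or a list with `chromosome`,
#'   `tss_bp`, `strand`.
#' @param genome a named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param length upstream window size in bp (default 2000).
#' @return List with `seq` (character, promoter orientation), `chromosome`,
#'   `start_bp`, `end_bp` (genomic 1-based inclusive bounds of the window)
#'   and `strand` (the gene's strand).
#' @export
extractUpstream <- function(gene, genome, length = 2000L) {
  g <- .asGeneRecord(gene)
  genome <- .asGenome(genome)
  if (!g$chromosome %in% names(genome))
    .stopf("chromosome '%s' not present in the genome", g$chromosome)
  chr_len <- nchar(as.character(genome[[g$chromosome]]))
  if (g$strand == "+") {
    start_bp <- g$tss_bp - length
    end_bp <- g$tss_bp - 1
    if (start_bp < 1) {
      .warnf("upstream window truncated at chromosome start (gene TSS %d)",
             g$tss_bp)
      start_bp <- 1
    }
  } else {
    start_bp <- g$tss_bp + 1
    end_bp <- g$tss_bp + length
    if (end_bp > chr_len) {
      .warnf("upstream window truncated at chromosome end (gene TSS %d)",
             g$tss_bp)
      end_bp <- chr_len
    }
  }
  if (end_bp < start_bp)
    return(list(seq = "", chromosome = g$chromosome,
                start_bp = NA_integer_, end_bp = NA_integer_,
                strand = g$strand))
  s <- substring(as.character(genome[[g$chromosome]]), start_bp, end_bp)
  if (g$strand == "-") s <- .revcomp(s)
  list(seq = toupper(s), chromosome = g$chromosome,
       start_bp = start_bp, end_bp = end_bp, strand = g$strand)
}

.asGeneRecord <- function(gene) {
  if (is(gene, "GRanges")) {
    stopifnot(length(gene) == 1)
    list(chromosome = as.character(seqnames(gene)),
         tss_bp = gene$tss_bp,
         strand = as.character(strand(gene)),
         gene_id = if (!is.null(gene$gene_id)) gene$gene_id else names(gene))
  } else {
    stopifnot(all(c("chromosome", "tss_bp", "strand") %in% names(gene)))
    gene
  }
}

.asGenome <- function(genome) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  # FASTA headers may carry descriptions after the identifier
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Scan gene upstream regions for motifs
#'
#' Extracts the upstream window of every gene and scans it with each motif on
#' both strands, mapping hits back to genomic coordinates.  A hit's genomic
#' strand is relative to the forward genome strand (a `+` hit on the
#' promoter-oriented sequence of a `-`-strand gene is a genomic `-` hit), and
#' the reported `match` carries forward-genome letters.
#'
#' @param genes [GenomicRanges::GRanges] of gene models (see
#'   [readGeneModels()]).
#' @param genome named [Biostrings::DNAStringSet] or FASTA path.
#' @param motifs named list of consensus strings (default [choreMotifs()]).
#' @param upstream upstream window size in bp (default 2000).
#' @param min_score minimum relative score (default 0.90).
#' @return `data.frame` with `gene_id`, `motif`, `chromosome`, `strand`,
#'   `start_bp`, `end_bp` (genomic, 1-based inclusive), `score`, `match`.
#' @export
scanGeneSet <- function(genes, genome, motifs = choreMotifs(),
                        upstream = 2000L, min_score = 0.90) {
  genome <- .asGenome(genome)
  pwms <- lapply(names(motifs), function(nm) pwmFromConsensus(motifs[[nm]], nm))
  names(pwms) <- names(motifs)
  rows <- list()
  for (i in seq_along(genes)) {
    up <- suppressWarnings(extractUpstream(genes[i], genome, upstream))
    if (!nzchar(up$seq)) next
    gid <- .asGeneRecord(genes[i])$gene_id
    for (nm in names(pwms)) {
      h <- scanSequence(up$seq, pwms[[nm]], min_score, both_strands = TRUE)
      if (!nrow(h)) next
      if (up$strand == "+") {
        g_start <- up$start_bp + h$start - 1L
        g_end <- up$start_bp + h$end - 1L
        g_strand <- h$strand
      } else {
        g_start <- up$end_bp - h$end + 1L
        g_end <- up$end_bp - h$start + 1L
        g_strand <- ifelse(h$strand == "+", "-", "+")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, motif = nm, chromosome = up$chromosome,
        strand = g_strand, start_bp = g_start, end_bp = g_end,
        score = h$score,
        match = substring(as.character(genome[[up$chromosome]]),
                          g_start, g_end))
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), motif = character(),
                      chromosome = character(), strand = character(),
                      start_bp = integer(), end_bp = integer(),
                      score = numeric(), match = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write motif hits (or QTL regions) as BED6
#'
#' Converts 1-based inclusive coordinates to BED's 0-based half-open
#' convention on write.
#'
#' @param x `data.frame` with `chromosome`, `start_bp`, `end_bp` and
#'   optionally `gene_id`/`top_marker` (name field), `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path) {
  name <- if (!is.null(x$gene_id)) x$gene_id
          else if (!is.null(x$top_marker)) x$top_marker else "."
  score <- if (!is.null(x$score)) x$score else 0
  strand <- if (!is.null(x$strand)) x$strand else "."
  bed <- data.frame(x$chromosome, x$start_bp - 1L, x$end_bp, name,
                    score, strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
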