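# readers and writers for the plain-text formats the pipeline consumes.
# All text readers transparently accept gzip-compressed files.

.GENO_TOKENS <- c(S1 = 2L, H = 1L, S2 = 0L)
.MISSING_TOKENS <- c("NA", "-", "")

#' Read a genotype matrix
#'
#' Reads a marker-by-animal genotype table.  The file must contain the
#' columns `marker_id`, `chromosome` and `position` (or `position_bp`),
#' followed by one column per animal.  Calls are either the tokens
#' `S1`/`H`/`S2` (founder-1 homozygote, heterozygote, founder-2 homozygote)
#' or the numeric codes `2`/`1`/`0`; `NA`, `-` and the empty string denote
#' missing calls.
#'
#' @param path TSV or CSV file (``.gz`` accepted); the separator is inferred
#'   from the extension unless `sep` is given.
#' @param sep optional field separator override.
#' @return A [GenotypeMatrix-class], sorted by (chromosome, position).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("marker_id\tchromosome\tposition\ta1\ta2",
#'              "m1\t1\t100\tS1\tH",
#'              "m2\t1\t200\tH\tS2",
#'              "m3\t1\t300\tS2\tS2"), f)
#' genotypeCalls(readGenotypes(f))
#' @export
readGenotypes <- function(path, sep = NULL) {
  sep <- .sepForPath(path, sep)
  con <- .openInput(path)
  on.exit(close(con))
  tab <- read.table(con, header = TRUE, sep = sep, colClasses = "character",
                    check.names = FALSE, na.strings = NULL,
                    comment.char = "", quote = "\"")
  names(tab)[names(tab) == "position"] <- "position_bp"
  need <- c("marker_id", "chromosome", "position_bp")
  if (!all(need %in% names(tab)))
    .stopf("genotype file needs columns %s", paste(need, collapse = ", "))
  animals <- setdiff(names(tab), need)
  if (!length(animals)) .stopf("genotype file has no animal columns")
  calls <- matrix(NA_integer_, nrow(tab), length(animals),
                  dimnames = list(tab$marker_id, animals))
  for (a in animals) {
    tok <- trimws(tab[[a]])
    val <- rep(NA_integer_, length(tok))
    known <- tok %in% names(.GENO_TOKENS)
    val[known] <- .GENO_TOKENS[tok[known]]
    numeric_tok <- tok %in% c("0", "1", "2")
    val[numeric_tok] <- as.integer(tok[numeric_tok])
    bad <- !known & !numeric_tok & !(tok %in% .MISSING_TOKENS)
    if (any(bad)) {
      i <- which(bad)[1]
      .stopf("invalid genotype call '%s' at marker '%s', animal '%s'",
             tok[i], tab$marker_id[i], a)
    }
    calls[, a] <- val
  }
  map <- data.frame(marker_id = tab$marker_id,
                    chromosome = tab$chromosome,
                    position_bp = as.numeric(tab$position_bp),
                    stringsAsFactors = FALSE)
  GenotypeMatrix(calls, map)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [readGenotypes()]: tokens `S1`/`H`/`S2`, missing written as
#' `NA`.  A write/read round trip reproduces the object exactly.
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
  stopifnot(is(x, "GenotypeMatrix"))
  m <- genotypeCalls(x)
  tok <- matrix(names(.GENO_TOKENS)[match(m, .GENO_TOKENS)],
                nrow(m), ncol(m), dimnames = dimnames(m))
  tok[is.na(m)] <- "NA"
  out <- cbind(markerMap(x), as.data.frame(tok, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weekly phenotype table
#'
#' Accepts either a long table with columns `animal_id`, `week`, `weight_g`
#' (aliases `animal`/`grams`/`weight` are recognized) or a wide table whose
#' first column is the animal id and remaining columns are weeks.  Missing
#' cells are preserved.
#'
#' @param path CSV or TSV file (``.gz`` accepted).
#' @param sep optional field separator override.
#' @return A [PhenotypeSeries-class].
#' @export
readPhenotypes <- function(path, sep = NULL) {
  sep <- .sepForPath(path, sep)
  con <- .openInput(path)
  on.exit(close(con))
  tab <- read.table(con, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  names(tab)[nm == "animal"] <- "animal_id"
  names(tab)[nm %in% c("grams", "weight")] <- "weight_g"
  if (all(c("animal_id", "week", "weight_g") %in% names(tab))) {
    key <- paste(tab$animal_id, tab$week)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      .stopf("duplicate (animal, week) record: %s", d)
    }
    if (any(!is.na(tab$weight_g) & tab$weight_g <= 0)) {
      i <- which(!is.na(tab$weight_g) & tab$weight_g <= 0)[1]
      .stopf("non-positive weight %.3f for animal '%s' week %s",
             tab$weight_g[i], tab$animal_id[i], tab$week[i])
    }
    animals <- unique(tab$animal_id)
    weeks <- sort(unique(as.integer(tab$week)))
    w <- matrix(NA_real_, length(animals), length(weeks),
                dimnames = list(animals, as.character(weeks)))
    w[cbind(match(tab$animal_id, animals),
            match(as.integer(tab$week), weeks))] <- tab$weight_g
    return(PhenotypeSeries(w, weeks))
  }
  # wide layout: first column = animal id, remaining columns = weeks
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    .stopf("duplicate animal id: %s", ids[duplicated(ids)][1])
  weeks <- suppressWarnings(as.integer(names(tab)[-1]))
  if (any(is.na(weeks)))
    .stopf("phenotype file is neither long (animal_id/week/weight_g) nor wide")
  w <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(w) <- "double"
  rownames(w) <- ids
  if (any(!is.na(w) & w <= 0)) .stopf("non-positive weight in phenotype file")
  ord <- order(weeks)
  PhenotypeSeries(w[, ord, drop = FALSE], weeks[ord])
}

#' Write a phenotype series
#'
#' @param x a [PhenotypeSeries-class].
#' @param path output file (CSV).
#' @param format `"long"` (animal_id, week, weight_g) or `"wide"`.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(x, path, format = c("long", "wide")) {
  stopifnot(is(x, "PhenotypeSeries"))
  format <- match.arg(format)
  w <- weightMatrix(x)
  if (format == "wide") {
    out <- data.frame(animal_id = rownames(w), w, check.names = FALSE)
  } else {
    out <- data.frame(
      animal_id = rep(rownames(w), times = ncol(w)),
      week = rep(phenoWeeks(x), each = nrow(w)),
      weight_g = as.vector(w))
    out <- out[!is.na(out$weight_g), , drop = FALSE]
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 or BED6
#'
#' Extracts gene-level models with a strand-resolved transcription start site
#' (TSS): the lower coordinate for `+` genes, the upper for `-` genes.  BED
#' input (0-based half-open) is converted to 1-based inclusive coordinates on
#' read.  A record without strand information is an error, because the TSS
#' cannot be resolved.
#'
#' @param path a `.gff`/`.gff3` or `.bed` file (``.gz`` accepted).
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `symbol` and `tss_bp`.
#' @export
readGeneModels <- function(path) {
  type <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
          else "gff"
  .validateFeatureLines(path, type)
  gr <- rtracklayer::import(path)
  if (type == "gff") {
    if ("type" %in% names(mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    id <- if (!is.null(gr$gene_id)) gr$gene_id
          else if (!is.null(gr$ID)) gr$ID else gr$Name
    sym <- if (!is.null(gr$Name)) gr$Name else id
  } else {
    id <- gr$name
    sym <- gr$name
  }
  if (any(strand(gr) == "*"))
    .stopf("%d gene record(s) without strand; TSS cannot be resolved",
           sum(strand(gr) == "*"))
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  mcols(out)$gene_id <- as.character(id)
  mcols(out)$symbol <- as.character(sym)
  mcols(out)$tss_bp <- ifelse(as.character(strand(gr)) == "+",
                              start(gr), end(gr))
  names(out) <- out$gene_id
  out
}

# minimal structural pre-check so malformed lines are reported by number
.validateFeatureLines <- function(path, type) {
  con <- .openInput(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  min_fields <- if (type == "bed") 6L else 9L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") ||
        (type == "bed" && grepl("^(track|browser)", ln))) next
    if (length(strsplit(ln, "\t")[[1]]) < min_fields)
      .stopf("malformed %s line %d: expected >= %d tab-separated fields",
             toupper(type), i, min_fields)
  }
  invisible(TRUE)
}

# closed vocabulary of variant-consequence classes used by the prioritization
.CONSEQUENCE_CLASSES <- c("deleterious_domain_missense",
                          "tolerated_domain_missense",
                          "utr", "promoter", "enhancer",
                          "ctcf_binding", "splice_site", "other")

#' Read variant-consequence annotations
#'
#' VEP-style per-variant consequence records, one row per (gene, variant).
#' Classes must come from the closed vocabulary
#' `r paste0('\x60', .CONSEQUENCE_CLASSES, '\x60', collapse = ", ")`.
#'
#' @param path TSV with columns `gene_id`, `variant_id`, `consequence_class`
#'   and optional `sift_score`.
#' @return `data.frame` of validated records (zero rows for a header-only
#'   file).
#' @export
readConsequences <- function(path) {
  con <- .openInput(path)
  on.exit(close(con))
  tab <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!nrow(tab)) {
    return(data.frame(gene_id = character(), variant_id = character(),
                      consequence_class = character(),
                      sift_score = numeric()))
  }
  need <- c("gene_id", "variant_id", "consequence_class")
  if (!all(need %in% names(tab)))
    .stopf("consequence file needs columns %s", paste(need, collapse = ", "))
  bad <- !(tab$consequence_class %in% .CONSEQUENCE_CLASSES)
  if (any(bad))
    .stopf("unknown consequence class '%s' (gene '%s')",
           tab$consequence_class[which(bad)[1]], tab$gene_id[which(bad)[1]])
  if (!"sift_score" %in% names(tab)) tab$sift_score <- NA_real_
  tab$sift_score <- as.numeric(tab$sift_score)
  tab[c("gene_id", "variant_id", "consequence_class", "sift_score")]
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene_id`, `tissue` (`gonadal_adipose` or
#'   `liver`), `fold_change` (S1/S2) and `p_value`.
#' @return Validated `data.frame`.
#' @export
readExpression <- function(path) {
  con <- .openInput(path)
  on.exit(close(con))
  tab <- read.table(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "fold_change", "p_value")
  if (!all(need %in% names(tab)))
    .stopf("expression file needs columns %s", paste(need, collapse = ", "))
  if (!all(tab$tissue %in% c("gonadal_adipose", "liver")))
    .stopf("tissue must be 'gonadal_adipose' or 'liver'")
  p <- tab$p_value
  if (any(!is.na(p) & (p < 0 | p > 1)))
    .stopf("p_value outside [0, 1]")
  if (any(!is.na(tab$fold_change) & tab$fold_change <= 0))
    .stopf("fold_change must be positive")
  tab[need]
}
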