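#' Marker-by-animal genotype container
#'
#' `GenotypeMatrix` holds biallelic genotype calls for an advanced intercross
#' line as a [SummarizedExperiment::RangedSummarizedExperiment] with a single
#' `"calls"` assay (markers are rows, animals are columns) and the marker map
#' as `rowRanges`.  Calls are coded `2` = homozygous for the founder-1 (S1)
#' allele, `1` = heterozygous, `0` = homozygous founder-2 (S2), `NA` = missing.
#' The S1 line is, by convention, the line whose allele increases the trait,
#' which fixes the sign of all downstream effect estimates.
#'
#' Markers are stored sorted by (chromosome, position); positions are 1-based
#' and strictly increasing within a chromosome.
#'
#' @slot ... inherits all slots from `RangedSummarizedExperiment`.
#'
#' @seealso [GenotypeMatrix()] (constructor), [genotypeCalls()],
#'   [markerMap()], [readGenotypes()]
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!("calls" %in% assayNames(object)))
    return("assay 'calls' is required")
  m <- assay(object, "calls")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "marker ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "animal ids (colnames) must be present and unique")
  bad <- !is.na(m) & !(m == 0 | m == 1 | m == 2)
  if (any(bad))
    msg <- c(msg, sprintf("%d call(s) outside {0,1,2,NA}", sum(bad)))
  chr <- as.character(seqnames(rowRanges(object)))
  pos <- start(rowRanges(object))
  if (any(pos < 1)) msg <- c(msg, "positions must be >= 1")
  for (c1 in unique(chr)) {
    p <- pos[chr == c1]
    if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, sprintf(
        "positions not strictly increasing on chromosome %s", c1))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls numeric/integer matrix of genotype codes (markers x animals)
#'   with values in `{0, 1, 2, NA}`; rownames are marker ids, colnames animal
#'   ids (alternatively supply them through `map` / `animal_ids`).
#' @param map `data.frame` with columns `marker_id`, `chromosome`,
#'   `position_bp` (1-based), one row per row of `calls`.
#' @param animal_ids optional character vector of animal ids (defaults to
#'   `colnames(calls)`).
#'
#' @details Rows are reordered so markers are sorted by chromosome (natural
#'   order) and position.  Duplicate marker ids or coincident positions on a
#'   chromosome are an error.
#'
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' calls <- matrix(c(2, 1, 1, 0, 0, 0), nrow = 3, byrow = TRUE)
#' map <- data.frame(marker_id = c("m1", "m2", "m3"),
#'                   chromosome = "1", position_bp = c(100, 200, 300))
#' g <- GenotypeMatrix(calls, map, animal_ids = c("a1", "a2"))
#' nMarkers(g)
#' @export
GenotypeMatrix <- function(calls, map, animal_ids = colnames(calls)) {
  stopifnot(is.matrix(calls), is.data.frame(map))
  need <- c("marker_id", "chromosome", "position_bp")
  if (!all(need %in% names(map)))
    .stopf("map needs columns %s", paste(need, collapse = ", "))
  if (nrow(map) != nrow(calls))
    .stopf("map has %d rows but calls has %d", nrow(map), nrow(calls))
  if (is.null(animal_ids))
    .stopf("animal ids are required (colnames of calls or animal_ids=)")
  dup <- map$marker_id[duplicated(map$marker_id)]
  if (length(dup))
    .stopf("duplicate marker id(s): %s", paste(unique(dup), collapse = ", "))
  ord <- order(.chromFactor(map$chromosome), map$position_bp)
  map <- map[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  storage.mode(calls) <- "integer"
  gr <- GRanges(as.character(map$chromosome),
                IRanges(map$position_bp, width = 1L))
  names(gr) <- map$marker_id
  dimnames(calls) <- list(map$marker_id, animal_ids)
  se <- SummarizedExperiment(assays = list(calls = calls), rowRanges = gr)
  new("GenotypeMatrix", se)
}

#' Weekly phenotype series container
#'
#' Holds one quantitative measurement (body weight in grams) per animal and
#' week of age.  Rows are animals, columns are weeks; missing cells are `NA`.
#'
#' @slot weights numeric matrix (animals x weeks), values > 0 or `NA`;
#'   rownames are animal ids.
#' @slot weeks integer vector of ages in weeks, strictly increasing, one per
#'   column of `weights`.
#'
#' @seealso [PhenotypeSeries()] (constructor), [weightMatrix()],
#'   [phenoWeeks()], [readPhenotypes()]
#' @export
setClass("PhenotypeSeries",
         representation(weights = "matrix", weeks = "integer"))

setValidity("PhenotypeSeries", function(object) {
  msg <- character()
  w <- object@weights
  if (is.null(rownames(w)) || anyDuplicated(rownames(w)))
    msg <- c(msg, "animal ids (rownames) must be present and unique")
  if (length(object@weeks) != ncol(w))
    msg <- c(msg, "one week per column is required")
  if (is.unsorted(object@weeks, strictly = TRUE))
    msg <- c(msg, "weeks must be strictly increasing")
  if (any(!is.na(w) & w <= 0))
    msg <- c(msg, "weights must be positive where present")
  if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeSeries
#'
#' @param weights numeric matrix (animals x weeks), positive or `NA`, with
#'   animal ids as rownames.
#' @param weeks integer vector of ages in weeks (defaults to numeric
#'   colnames of `weights`).
#' @return A [PhenotypeSeries-class] object.
#' @examples
#' w <- matrix(c(11, 17.3), nrow = 1, dimnames = list("a1", c("3", "4")))
#' PhenotypeSeries(w)
#' @export
PhenotypeSeries <- function(weights, weeks = as.integer(colnames(weights))) {
  stopifnot(is.matrix(weights))
  weeks <- as.integer(weeks)
  colnames(weights) <- as.character(weeks)
  new("PhenotypeSeries", weights = weights, weeks = weeks)
}

# ---- generics ----------------------------------------------------------

#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix` or `PhenotypeSeries`
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @rdname PhenotypeSeries-class
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname PhenotypeSeries-class
#' @export
setGeneric("phenoWeeks", function(x) standardGeneric("phenoWeeks"))

# ---- methods -----------------------------------------------------------

#' @rdname GenotypeMatrix-class
#' @export
setMethod("animalIds", "GenotypeMatrix", function(x) colnames(x))

#' @rdname PhenotypeSeries-class
#' @param x a `PhenotypeSeries`
#' @export
setMethod("animalIds", "PhenotypeSeries", function(x) rownames(x@weights))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) rownames(x))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerMap", "GenotypeMatrix", function(x) {
  gr <- rowRanges(x)
  data.frame(marker_id = names(gr),
             chromosome = as.character(seqnames(gr)),
             position_bp = start(gr),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) assay(x, "calls"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) nrow(x))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nAnimals", "GenotypeMatrix", function(x) ncol(x))

#' @rdname PhenotypeSeries-class
#' @export
setMethod("weightMatrix", "PhenotypeSeries", function(x) x@weights)

#' @rdname PhenotypeSeries-class
#' @export
setMethod("phenoWeeks", "PhenotypeSeries", function(x) x@weeks)

#' @rdname PhenotypeSeries-class
#' @export
setMethod("nAnimals", "PhenotypeSeries", function(x) nrow(x@weights))

setMethod("show", "GenotypeMatrix", function(object) {
  chr <- unique(as.character(seqnames(rowRanges(object))))
  m <- assay(object, "calls")
  cat(sprintf("GenotypeMatrix: %d markers x %d animals (%d chromosome%s)\n",
              nrow(object), ncol(object), length(chr),
              if (length(chr) == 1) "" else "s"))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(m))))
})

setMethod("show", "PhenotypeSeries", function(object) {
  cat(sprintf("PhenotypeSeries: %d animals, weeks %d-%d (%d time points)\n",
              nrow(object@weights), min(object@weeks), max(object@weeks),
              length(object@weeks)))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(object@weights))))
})
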