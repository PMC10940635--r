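# shared internal helpers

# natural chromosome ordering: numeric chromosomes first in numeric order,
# then the rest alphabetically (X, Y, MT, ...)
.chromLevels <- function(chr) {
  u <- unique(as.character(chr))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), num, u)]
}

.chromFactor <- function(chr) factor(as.character(chr), levels = .chromLevels(chr))

# connection that transparently handles .gz paths for the text readers
.openInput <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.sepForPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
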