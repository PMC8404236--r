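#' Round half up
#'
#' Decimal rounding with ties away from zero, matching how the published
#' frequency tables print percentages (base R's `round()` rounds half to
#' even).  A tiny epsilon guards against binary representation of values
#' such as `0.015` falling just below the half-way point.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @examples
#' roundHalfUp(c(0.005, 0.015, 3.9275) * 100, 2)
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# random DNA of length n (uniform base composition)
.randDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random DNA containing no tandem GAA run of >= maxTriplets triplets,
# so synthetic flanks cannot mimic the repeat tract
.noGaaDna <- function(n, maxTriplets = 3) {
  repeat {
    s <- .randDna(n)
    if (countGaaRepeats(s) <= maxTriplets) return(s)
  }
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.provenanceHeader <- function(seed = NA, ...) {
  extra <- c(...)
  kv <- if (length(extra)) paste(names(extra), unname(extra), sep = "=", collapse = " ") else ""
  trimws(sprintf("# ampliscreen %s seed=%s %s",
                 as.character(utils::packageVersion("ampliscreen")),
                 as.character(seed), kv))
}

#' Write reads as FASTQ
#'
#' @param reads named character vector of read sequences; names become
#'   FASTQ record ids.
#' @param path output file (`.gz` suffix triggers gzip).
#' @param quality single quality character replicated across each read.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path, quality = "I") {
  dna <- Biostrings::DNAStringSet(unname(as.character(reads)))
  names(dna) <- if (is.null(names(reads)))
    sprintf("read%d", seq_along(reads)) else names(reads)
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(dna), function(w)
    strrep(quality, w), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file (optionally gzipped).
#' @return named character vector of read sequences.
#' @export
readFastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(dna)
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}
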