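#' Path to a packaged fixture table
#'
#' The package ships three plain-text fixtures transcribed from the source
#' frequency tables: `"manifest"` (the 40-variant screening panel),
#' `"table1"` (carrier counts in the 100%-Syrian cohort with Ashkenazi
#' comparison) and `"table3"` (carrier counts in the mixed Syrian, Iranian
#' and Ashkenazi cohorts).
#'
#' @param name one of `"manifest"`, `"table1"`, `"table3"`.
#' @return path to the installed TSV file.
#' @examples
#' basename(screeningFixture("table1"))
#' @export
screeningFixture <- function(name = c("manifest", "table1", "table3")) {
  name <- match.arg(name)
  fn <- c(manifest = "panel_manifest.tsv", table1 = "table1.tsv",
          table3 = "table3.tsv")[[name]]
  path <- system.file("extdata", fn, package = "ampliscreen")
  if (!nzchar(path)) .stopf("fixture '%s' not installed", name)
  path
}

# expected md5 digests of the shipped fixtures; reproducePanelReport()
# refuses to recompute published numbers from a tampered copy
.FIXTURE_MD5 <- c(
  panel_manifest.tsv = "ccb1ac6eb2024b975a0de8369ee6b2b9",
  table1.tsv = "397b7efea604c1e69b8037a577d1531b",
  table3.tsv = "59cbc2e5509314206937b79d936ff50c")

.variantTypeOf <- function(ref, alt) {
  ifelse(grepl(">>", alt, fixed = TRUE), "expansion",
  ifelse(ref == "." | alt == "." | ref == "" | alt == "", "cnv",
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snv",
  ifelse(nchar(ref) > nchar(alt), "del",
  ifelse(nchar(ref) < nchar(alt), "ins", "mnv")))))
}

.MANIFEST_COLS <- c("variant_id", "chrom", "pos_hg38", "end_hg38", "ref",
                    "alt", "gene", "omim", "hgvs_c", "hgvs_p", "phenotype",
                    "category")

# strict TSV split (UTF-8, tab, no quoting); comment lines start with '#'
.readTsvLines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(lines)
  which0 <- which(keep)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = which0)
}

#' Read a screening-panel manifest
#'
#' Parses a tab-separated manifest of panel variants into a
#' [VariantPanel-class].  Chromosome labels are normalised to `chrN` form
#' and positions are kept 1-based as printed (VCF convention).  The
#' `category` column (1-5) is optional per row; region-level records use
#' `.` for both alleles and may carry an `end_hg38` column.
#'
#' @param path manifest TSV with columns `variant_id`, `chrom`, `pos_hg38`,
#'   `end_hg38` (optional), `ref`, `alt`, `gene`, `omim`, `hgvs_c`,
#'   `hgvs_p`, `phenotype`, `category` (optional).
#' @return a [VariantPanel-class].
#' @examples
#' panel <- readPanelManifest(screeningFixture("manifest"))
#' length(panel)
#' @export
readPanelManifest <- function(path) {
  if (!file.exists(path)) .stopf("manifest file not found: %s", path)
  tl <- .readTsvLines(path)
  if (!length(tl$fields)) .stopf("manifest is empty: %s", path)
  header <- tl$fields[[1]]
  if (!all(setdiff(.MANIFEST_COLS, c("end_hg38", "category")) %in% header))
    .stopf("manifest header lacks required columns (line %d)", tl$lineno[1])
  rows <- tl$fields[-1]
  linenos <- tl$lineno[-1]
  nh <- length(header)
  rec <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < nh - 2 || length(f) > nh)
      .stopf("malformed manifest row at line %d: %d fields, expected %d",
             linenos[i], length(f), nh)
    f <- c(f, rep("", nh - length(f)))     # trailing optional fields
    names(f) <- header
    rec[[i]] <- f
  }
  df <- as.data.frame(do.call(rbind, rec), stringsAsFactors = FALSE)
  if (!nrow(df)) df <- as.data.frame(setNames(rep(list(character(0)), nh), header))
  pos <- suppressWarnings(as.integer(df$pos_hg38))
  if (nrow(df) && any(is.na(pos) | pos <= 0))
    .stopf("malformed manifest row at line %d: bad position '%s'",
           linenos[which(is.na(pos) | pos <= 0)[1]],
           df$pos_hg38[which(is.na(pos) | pos <= 0)[1]])
  dup <- duplicated(df$variant_id)
  if (any(dup))
    .stopf("duplicate variant_id in manifest: %s",
           paste(unique(df$variant_id[dup]), collapse = ", "))
  chrom <- ifelse(startsWith(df$chrom, "chr"), df$chrom, paste0("chr", df$chrom))
  type <- .variantTypeOf(df$ref, df$alt)
  end <- if ("end_hg38" %in% names(df))
    suppressWarnings(as.integer(df$end_hg38)) else rep(NA_integer_, nrow(df))
  end <- ifelse(is.na(end), pos + pmax(nchar(df$ref), 1L) - 1L, end)
  category <- if ("category" %in% names(df))
    suppressWarnings(as.integer(df$category)) else rep(NA_integer_, nrow(df))
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(df)) chrom else character(0),
    ranges = IRanges::IRanges(start = pos, end = end),
    variant_id = df$variant_id, ref = df$ref, alt = df$alt, gene = df$gene,
    omim = df$omim, hgvs_c = df$hgvs_c, hgvs_p = df$hgvs_p,
    phenotype = df$phenotype, category = category, type = type)
  methods::new("VariantPanel", gr)
}

#' Write a screening-panel manifest
#'
#' Inverse of [readPanelManifest()]: a panel written and re-read yields an
#' identical `VariantPanel`.
#'
#' @param panel a [VariantPanel-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePanelManifest <- function(panel, path) {
  stopifnot(methods::is(panel, "VariantPanel"))
  mc <- S4Vectors::mcols(panel)
  haveEnd <- GenomicRanges::end(panel) !=
    GenomicRanges::start(panel) + pmax(nchar(mc$ref), 1L) - 1L
  df <- data.frame(
    variant_id = mc$variant_id,
    chrom = as.character(GenomicRanges::seqnames(panel)),
    pos_hg38 = GenomicRanges::start(panel),
    end_hg38 = ifelse(haveEnd, as.character(GenomicRanges::end(panel)), ""),
    ref = mc$ref, alt = mc$alt, gene = mc$gene, omim = mc$omim,
    hgvs_c = mc$hgvs_c, hgvs_p = mc$hgvs_p, phenotype = mc$phenotype,
    category = ifelse(is.na(mc$category), "", as.character(mc$category)),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.parseKN <- function(x, lineno) {
  out <- matrix(NA_integer_, length(x), 2, dimnames = list(NULL, c("carriers", "n")))
  live <- !(x %in% c("ND", "N/A", "", NA))
  m <- regmatches(x[live], regexec("^([0-9]+)/([0-9]+)$", x[live]))
  bad <- lengths(m) != 3
  if (any(bad))
    .stopf("malformed carrier count '%s' at line %d", x[live][bad][1],
           lineno[live][bad][1])
  out[live, "carriers"] <- as.integer(vapply(m, `[`, character(1), 2))
  out[live, "n"] <- as.integer(vapply(m, `[`, character(1), 3))
  over <- live & out[, "carriers"] > out[, "n"]
  if (any(over, na.rm = TRUE))
    .stopf("carriers exceed cohort size ('%s') at line %d",
           x[which(over)[1]], lineno[which(over)[1]])
  out
}

#' Read a published cohort frequency table
#'
#' Parses a fixture table whose population columns hold `"k/n"` carrier
#' counts (or `"ND"`, no data) alongside the printed percent, into one row
#' per variant x population.  Printed percents are cross-checked against
#' `100*carriers/n`; a discrepancy beyond 0.005 raises a warning, not an
#' error.
#'
#' @param path fixture TSV (see [screeningFixture()]).
#' @param populations names of the population count columns to extract;
#'   each must have a companion `<population>_pct` column.
#' @return data.frame with columns `variant_id`, `gene`, `phenotype`,
#'   `category` (if present), `population`, `carriers`, `n`,
#'   `percent_printed`.  `ND` entries yield `NA` counts.
#' @examples
#' t1 <- readCohortTable(screeningFixture("table1"),
#'                       populations = c("syrian_full", "ashkenazi"))
#' subset(t1, variant_id == "COL6A2:c.1402C>T")
#' @export
readCohortTable <- function(path, populations) {
  if (!file.exists(path)) .stopf("cohort table not found: %s", path)
  tl <- .readTsvLines(path)
  header <- tl$fields[[1]]
  rows <- tl$fields[-1]
  linenos <- tl$lineno[-1]
  bad <- vapply(rows, length, 1L) != length(header)
  if (any(bad))
    .stopf("malformed table row at line %d", linenos[bad][1])
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  miss <- setdiff(c(populations, paste0(populations, "_pct")), header)
  if (length(miss))
    .stopf("table lacks population columns: %s", paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(populations, function(p) {
    kn <- .parseKN(df[[p]], linenos)
    pct <- suppressWarnings(as.numeric(df[[paste0(p, "_pct")]]))
    data.frame(variant_id = df$variant_id, gene = df$gene,
               phenotype = df$phenotype,
               category = if ("category" %in% header)
                 as.integer(df$category) else NA_integer_,
               population = p, carriers = kn[, "carriers"], n = kn[, "n"],
               percent_printed = pct, stringsAsFactors = FALSE)
  }))
  chk <- !is.na(out$carriers) & !is.na(out$percent_printed)
  dev <- abs(out$percent_printed[chk] -
             roundHalfUp(100 * out$carriers[chk] / out$n[chk], 2))
  if (any(dev > 0.005))
    warning(sprintf("printed percent deviates from carriers/n for %s",
                    paste(out$variant_id[chk][dev > 0.005], collapse = ", ")))
  rownames(out) <- NULL
  out
}
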