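#' Read a genetic linkage map
#'
#' Reads a three-column delimited text file (chromosome, marker id, position
#' in centiMorgans) and returns a validated map, sorted by chromosome and
#' position.  The field separator (comma or tab) is auto-detected.
#'
#' @param path Path to a delimited text file with columns
#'   `chromosome`, `marker`, `position` (header required).
#' @return A `data.frame` of class `"genetic_map"` with columns
#'   `chromosome` (character), `marker` (character) and `position`
#'   (numeric, cM), sorted by chromosome then position.
#' @export
read_genetic_map <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 3L)
    stop("genetic map must have 3 columns: chromosome, marker, position")
  names(df)[1:3] <- c("chromosome", "marker", "position")
  genetic_map(df$chromosome, df$marker, df$position)
}

#' Construct a genetic map object
#'
#' @param chromosome Chromosome labels (one per marker).
#' @param marker Unique marker identifiers.
#' @param position Map positions in centiMorgans (non-negative).
#' @return A sorted, validated `genetic_map` data frame.
#' @export
genetic_map <- function(chromosome, marker, position) {
  chromosome <- as.character(chromosome)
  marker <- as.character(marker)
  position <- as.numeric(position)
  if (anyNA(position)) stop("non-numeric or missing map position")
  if (any(position < 0)) stop("map positions must be non-negative")
  if (anyDuplicated(marker))
    stop("duplicated marker id: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  ord <- order(factor(chromosome, levels = unique(chromosome)), position)
  map <- data.frame(chromosome = chromosome[ord], marker = marker[ord],
                    position = position[ord], stringsAsFactors = FALSE)
  # positions must be distinguishable within a chromosome
  for (chr in unique(map$chromosome)) {
    p <- map$position[map$chromosome == chr]
    if (any(diff(p) < 0)) stop("decreasing positions on chromosome ", chr)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Write a genetic map to delimited text
#' @param map A `genetic_map`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_genetic_map <- function(map, path, sep = "\t") {
  utils::write.table(as.data.frame(map)[, c("chromosome", "marker", "position")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix aligned to a genetic map
#'
#' Genotypes are coded `0` (first-parent homozygote), `1` (second-parent
#' homozygote) or `NA`.  The file must have a `line` column (or the first
#' column is taken as line ids) followed by one column per marker; marker
#' columns are re-ordered to match the map.  Heterozygote or other codes are
#' rejected unless `drop_het = TRUE`, in which case they are set to missing.
#'
#' @param path Path to delimited text (comma or tab).
#' @param map A `genetic_map` the columns must align to.
#' @param drop_het If `TRUE`, non-`{0,1,NA}` codes are converted to `NA`
#'   instead of raising an error.
#' @return An integer matrix (lines x markers) with line ids as rownames and
#'   marker ids as colnames, in map order.
#' @export
read_genotypes <- function(path, map, drop_het = FALSE) {
  df <- read_delim_auto(path)
  line_id <- as.character(df[[1L]])
  g <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(g) <- "numeric"
  rownames(g) <- line_id
  missing_in_map <- setdiff(colnames(g), map$marker)
  if (length(missing_in_map))
    stop("markers absent from map: ", paste(missing_in_map, collapse = ", "))
  bad <- !(g %in% c(0, 1)) & !is.na(g)
  if (any(bad)) {
    if (drop_het) g[bad] <- NA
    else stop("non-biallelic-homozygote genotype code found (e.g. \"",
              g[which(bad)[1L]], "\"); use drop_het = TRUE to set to NA")
  }
  align_genotypes(g, map)
}

#' @keywords internal
align_genotypes <- function(g, map) {
  keep <- map$marker[map$marker %in% colnames(g)]
  g <- g[, keep, drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

#' Write a genotype matrix
#' @param geno Lines x markers matrix in `{0,1,NA}`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_genotypes <- function(geno, path, sep = "\t") {
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long-format plot phenotypes
#'
#' Expected columns: `line`, `is_check`, `row`, `column`, `tp` (days after
#' sowing) and `value`.  `(row, column, tp)` combinations must be unique.
#'
#' @param path Path to delimited text.
#' @return A `data.frame` of class `"pheno_long"`.
#' @export
read_pheno_long <- function(path) {
  df <- read_delim_auto(path)
  need <- c("line", "is_check", "row", "column", "tp", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  pheno_long(df[, need])
}

#' Validate a long-format phenotype table
#' @param df Data frame with columns line, is_check, row, column, tp, value.
#' @return The validated `pheno_long` data frame.
#' @export
pheno_long <- function(df) {
  df$line <- as.character(df$line)
  df$is_check <- as.logical(df$is_check)
  df$row <- as.integer(df$row)
  df$column <- as.integer(df$column)
  df$tp <- as.integer(df$tp)
  df$value <- as.numeric(df$value)
  key <- paste(df$row, df$column, df$tp)
  if (anyDuplicated(key)) stop("duplicate (row, column, tp) plot records")
  class(df) <- c("pheno_long", "data.frame")
  df
}

#' Write long-format plot phenotypes
#' @param pheno A `pheno_long` data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_pheno_long <- function(pheno, path, sep = "\t") {
  utils::write.table(as.data.frame(pheno), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter markers by call rate, minor allele frequency and redundancy
#'
#' Markers with call rate below `call_rate_min` are removed first; remaining
#' missing calls are imputed by the per-marker mode (inbred biallelic data);
#' markers with minor allele frequency below `maf_min` are then removed;
#' finally exact-duplicate marker columns are collapsed, keeping the first in
#' map order.  The defaults (call rate 0.90, MAF 0.01) are the conventional
#' thresholds for SNP-array data in inbred mapping populations.
#'
#' @param geno Lines x markers matrix in `{0,1,NA}`.
#' @param map Optional `genetic_map`; if supplied, it is subset in step with
#'   the genotypes and returned.
#' @param call_rate_min Minimum proportion of non-missing calls per marker.
#' @param maf_min Minimum minor allele frequency.
#' @param drop_redundant Collapse exact-duplicate columns?
#' @return A list with `geno` (filtered, imputed matrix), `map` (subset map
#'   or `NULL`) and `report` (counts removed per rule and number of imputed
#'   calls).
#' @export
filter_markers <- function(geno, map = NULL, call_rate_min = 0.90,
                           maf_min = 0.01, drop_redundant = TRUE) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  report <- list(low_call_rate = 0L, low_maf = 0L, duplicates = 0L,
                 imputed_calls = 0L)

  call_rate <- 1 - colMeans(is.na(geno))
  keep <- call_rate >= call_rate_min
  report$low_call_rate <- sum(!keep)
  if (!any(keep)) stop("all markers removed by the call-rate filter")
  geno <- geno[, keep, drop = FALSE]

  # mode imputation per marker: deterministic, ties -> 0
  nmiss <- sum(is.na(geno))
  if (nmiss > 0) {
    for (j in which(colSums(is.na(geno)) > 0)) {
      x <- geno[, j]
      mode_call <- if (mean(x == 1, na.rm = TRUE) > 0.5) 1L else 0L
      geno[is.na(x), j] <- mode_call
    }
    report$imputed_calls <- nmiss
  }

  p <- colMeans(geno)
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  report$low_maf <- sum(!keep)
  if (!any(keep)) stop("all markers removed by the MAF filter")
  geno <- geno[, keep, drop = FALSE]

  if (drop_redundant) {
    key <- apply(geno, 2L, paste, collapse = "")
    dup <- duplicated(key)
    report$duplicates <- sum(dup)
    if (all(dup)) stop("all markers removed by the redundancy filter")
    geno <- geno[, !dup, drop = FALSE]
  }

  if (!is.null(map)) {
    map <- map[map$marker %in% colnames(geno), , drop = FALSE]
    class(map) <- c("genetic_map", "data.frame")
  }
  list(geno = geno, map = map, report = report)
}

# auto-detect comma vs tab separated text
#' @keywords internal
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

#' Write a results table with a YAML parameter header
#'
#' Writes `params` as a commented YAML block followed by the delimited table,
#' so every results artefact records the parameters that produced it.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param params Named list recorded in the header.
#' @export
write_result_table <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params)) {
    hdr <- strsplit(yaml::as.yaml(params), "\n")[[1L]]
    writeLines(paste("#", hdr), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_result_table()]
#' @param path Path written by `write_result_table`.
#' @return The data frame, with the parsed header in attribute `"params"`.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  params <- if (any(hdr))
    yaml::yaml.load(paste(sub("^# ?", "", lines[hdr]), collapse = "\n"))
  else list()
  df <- utils::read.table(text = lines[!hdr], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "params") <- params
  df
}
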