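# Readers and writers for the external formats: MAF-like SNV tables, minimal
# VCF, COSMIC-v2 signature catalogs, PPI edge lists, exposure tables, and
# JSON model files.

MAF_REQUIRED <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                  "Reference_Allele", "Tumor_Seq_Allele2")

.norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read somatic SNVs from a MAF-like TSV
#'
#' Parses a tab-separated mutation table with at least the columns
#' `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`, `Reference_Allele`
#' and `Tumor_Seq_Allele2` (optionally `Hugo_Symbol` and `ref_context`).
#' Only single-nucleotide substitutions are kept: rows with multi-base or
#' non-ACGT alleles, or with identical ref and alt, are skipped and counted.
#'
#' @param path Path to the TSV file.
#' @return A data frame of mutation records with columns `sample_id`, `chrom`
#'   (leading `"chr"` stripped), `pos` (1-based), `ref`, `alt`, `gene`,
#'   `context` (`NA` when absent), in file order. The number of skipped
#'   non-SNV rows is attached as attribute `"n_skipped"` and reported via
#'   `message()`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if (nrow(df) == 0L && ncol(df) <= 1L) {
    warning("empty MAF file: ", path)
    return(.empty_records())
  }
  missing_cols <- setdiff(MAF_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("MAF is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ref <- toupper(as.character(df$Reference_Allele))
  alt <- toupper(as.character(df$Tumor_Seq_Allele2))
  is_snv <- ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0L) {
    message("read_maf: skipped ", n_skipped, " non-SNV row(s)")
  }
  records <- data.frame(
    sample_id = as.character(df$Tumor_Sample_Barcode)[is_snv],
    chrom = .norm_chrom(df$Chromosome)[is_snv],
    pos = as.integer(df$Start_Position)[is_snv],
    ref = ref[is_snv],
    alt = alt[is_snv],
    gene = if ("Hugo_Symbol" %in% names(df))
      as.character(df$Hugo_Symbol)[is_snv] else "",
    context = if ("ref_context" %in% names(df))
      toupper(as.character(df$ref_context))[is_snv] else NA_character_,
    stringsAsFactors = FALSE
  )
  if (nrow(records) == 0L && n_skipped == 0L) warning("MAF contains no rows")
  attr(records, "n_skipped") <- n_skipped
  records
}

.empty_records <- function() {
  structure(data.frame(sample_id = character(0), chrom = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0), gene = character(0),
                       context = character(0), stringsAsFactors = FALSE),
            n_skipped = 0L)
}

#' Write mutation records as a MAF-like TSV
#'
#' Inverse of [read_maf()]; round-trips the record table.
#' @param records Data frame as returned by [read_maf()].
#' @param path Output path.
#' @export
write_maf <- function(records, path) {
  out <- data.frame(
    Tumor_Sample_Barcode = records$sample_id,
    Chromosome = records$chrom,
    Start_Position = records$pos,
    Reference_Allele = records$ref,
    Tumor_Seq_Allele2 = records$alt,
    Hugo_Symbol = records$gene,
    ref_context = records$context,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF of SNVs
#'
#' Accepts a plain-text VCF and keeps only the first five columns
#' (CHROM, POS, ID, REF, ALT); rows with non-SNV alleles are skipped.
#'
#' @param path Path to the VCF.
#' @param sample_id Sample barcode to assign to every record.
#' @return Mutation record data frame as in [read_maf()].
#' @export
read_vcf_minimal <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty VCF: ", path)
    return(.empty_records())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5L)) {
    stop("malformed VCF row(s): fewer than 5 columns at line ",
         which(lengths(fields) < 5L)[1])
  }
  ref <- toupper(vapply(fields, `[[`, "", 4L))
  alt <- toupper(vapply(fields, `[[`, "", 5L))
  is_snv <- ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  if (any(!is_snv)) message("read_vcf_minimal: skipped ", sum(!is_snv),
                            " non-SNV row(s)")
  records <- data.frame(
    sample_id = sample_id,
    chrom = .norm_chrom(vapply(fields, `[[`, "", 1L))[is_snv],
    pos = as.integer(vapply(fields, `[[`, "", 2L))[is_snv],
    ref = ref[is_snv], alt = alt[is_snv],
    gene = "", context = NA_character_,
    stringsAsFactors = FALSE
  )
  attr(records, "n_skipped") <- sum(!is_snv)
  records
}

#' Construct a signature catalog
#'
#' @param mat Numeric matrix, signatures x 96, rows non-negative. Rows are
#'   renormalized to sum to 1 when off by at most `renorm_tol`, otherwise an
#'   error is raised.
#' @param names Signature identifiers (default: rownames of `mat`).
#' @param renorm_tol Maximum tolerated deviation of a row sum from 1.
#' @return An object of class `signature_catalog` with elements `names`,
#'   `matrix` (rows sum to 1) and `channel_order`.
#' @export
signature_catalog <- function(mat, names = rownames(mat), renorm_tol = 1e-3) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 96L) stop("signature matrix must have 96 columns")
  if (is.null(names)) names <- paste0("S", seq_len(nrow(mat)))
  if (any(mat < 0)) stop("negative probability in signature matrix")
  rs <- rowSums(mat)
  off <- abs(rs - 1) > renorm_tol
  if (any(off)) {
    stop("signature row(s) ", paste(names[off], collapse = ", "),
         " do not sum to 1 within ", renorm_tol)
  }
  mat <- mat / rs
  dimnames(mat) <- list(names, CHANNELS96)
  structure(list(names = names, matrix = mat, channel_order = CHANNELS96),
            class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("signature_catalog:", length(x$names), "signatures x 96 channels\n")
  cat("  ", paste(utils::head(x$names, 8), collapse = ", "),
      if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a COSMIC-v2-layout signature catalog
#'
#' Expects a TSV with columns `Substitution Type`, `Trinucleotide`,
#' `Somatic Mutation Type`, then one column per signature; exactly 96
#' channel rows. Rows are reordered into the canonical channel order and
#' each signature column is renormalized to sum to 1 (tolerance `1e-3`).
#'
#' @param path Path to the TSV.
#' @return A [signature_catalog()].
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("Substitution Type", "Trinucleotide", "Somatic Mutation Type")
  if (!all(needed %in% names(df))) {
    stop("catalog is missing required column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  if (nrow(df) != 96L) {
    stop("catalog must have exactly 96 channel rows, found ", nrow(df))
  }
  ord <- match(CHANNELS96, df[["Somatic Mutation Type"]])
  if (anyNA(ord)) stop("catalog channel labels do not cover the 96 canonical channels")
  sig_cols <- setdiff(names(df), needed)
  if (length(sig_cols) == 0L) stop("catalog contains no signature columns")
  mat <- t(as.matrix(df[ord, sig_cols, drop = FALSE]))
  if (any(mat < 0)) stop("negative probability in catalog")
  signature_catalog(mat, names = sig_cols)
}

#' Write a signature catalog in COSMIC-v2 layout
#'
#' @param catalog A [signature_catalog()].
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "signature_catalog"))
  sub <- substr(CHANNELS96, 3L, 5L)
  tri <- paste0(substr(CHANNELS96, 1L, 1L), substr(CHANNELS96, 3L, 3L),
                substr(CHANNELS96, 7L, 7L))
  out <- data.frame(`Substitution Type` = sub, Trinucleotide = tri,
                    `Somatic Mutation Type` = CHANNELS96,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(t(catalog$matrix)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a protein-protein interaction network
#'
#' Gene symbols are trimmed and uppercased; self-loops and duplicate
#' (undirected) edges are removed.
#'
#' @param from,to Character vectors of interacting gene symbols.
#' @param genes Optional universe of genes; defaults to the edge endpoints.
#' @return An object of class `ppi_network` with elements `genes` (character)
#'   and `edges` (data frame with columns `from`, `to`).
#' @export
ppi_network <- function(from = character(0), to = character(0), genes = NULL) {
  from <- toupper(trimws(as.character(from)))
  to <- toupper(trimws(as.character(to)))
  stopifnot(length(from) == length(to))
  keep <- from != to & nzchar(from) & nzchar(to)
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  key <- !duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(from = a[key], to = b[key], stringsAsFactors = FALSE)
  if (is.null(genes)) genes <- unique(c(edges$from, edges$to))
  else genes <- unique(toupper(trimws(genes)))
  structure(list(genes = genes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$genes), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read a PPI edge list
#'
#' Two-column TSV of gene symbols with an optional third numeric confidence
#' column. Edges are undirected and deduplicated; self-loops are dropped.
#'
#' @param path Path to the edge list.
#' @param min_confidence Optional confidence cutoff; edges with confidence
#'   below it are dropped. Ignored when the file has no third column.
#' @param header Does the file carry a header row?
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path, min_confidence = NULL, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines)) lines <- lines[-1]
  if (length(lines) == 0L) return(ppi_network())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop("malformed edge-list row at line ", bad[1] + as.integer(header),
         ": expected at least 2 tab-separated columns")
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  if (!is.null(min_confidence)) {
    has_conf <- lengths(fields) >= 3L
    conf <- rep(NA_real_, length(fields))
    conf[has_conf] <- as.numeric(vapply(fields[has_conf], `[[`, "", 3L))
    keep <- !is.na(conf) & conf >= min_confidence
    from <- from[keep]; to <- to[keep]
  }
  ppi_network(from, to)
}

#' Write / read per-sample exposure tables
#'
#' Exposures are stored as a TSV with a `sample_id` column followed by one
#' column per signature.
#'
#' @param exposures Numeric matrix, samples x signatures, with dimnames.
#' @param path File path.
#' @return `read_exposures` returns the exposures matrix.
#' @export
write_exposures <- function(exposures, path) {
  out <- data.frame(sample_id = rownames(exposures),
                    as.data.frame(exposures, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposures
#' @export
read_exposures <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("sample_id" %in% names(df))
  mat <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(mat) <- df$sample_id
  mat
}

#' Serialize / restore a fitted one-vs-rest model as JSON
#'
#' @param model A `cancer_model` from [fit_one_vs_rest()].
#' @param path File path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cancer_model"))
  payload <- list(
    type_name = model$type_name,
    feature_names = model$feature_names,
    coefficients = model$coefficients,
    intercept = model$intercept,
    ridge = model$ridge,
    training_meta = model$training_meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    type_name = payload$type_name,
    feature_names = as.character(payload$feature_names),
    coefficients = as.numeric(payload$coefficients),
    intercept = as.numeric(payload$intercept),
    ridge = isTRUE(payload$ridge),
    training_meta = payload$training_meta
  ), class = "cancer_model")
}
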