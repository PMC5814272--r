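#' Readers and writers for the pipeline's file formats
#'
#' The pipeline exchanges data through plain-text formats: MAF-like
#' tab-separated mutation tables, GMT gene-set files, TSV expression
#' matrices (genes x samples, linear-scale normalized values), protein
#' FASTA, a class-I HLA genotype TSV (6 alleles per sample) and a clinical
#' TSV. All readers validate strictly and fail with classed conditions
#' (`neoimmune_format_error` for malformed files,
#' `neoimmune_record_error` for invalid individual records). Gzipped files
#' (`.gz`) are read and written transparently.
#'
#' @name io_formats
NULL

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                     "silent", "other")

# cBioPortal / GDC-style MAF headers mapped onto our normalized classes.
MAF_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift",
  Frame_Shift_Ins   = "frameshift",
  Splice_Site       = "splice",
  Splice_Region     = "splice",
  Silent            = "silent"
)

#' Default MAF column mapping
#'
#' Maps internal mutation-record fields to MAF header names. MAF dialects
#' vary; pass a modified copy of this list to [read_maf()] to adapt.
#'
#' @return Named list: internal field -> expected column name.
#' @export
maf_col_map <- function() {
  list(
    sample_id              = "Tumor_Sample_Barcode",
    hugo_symbol            = "Hugo_Symbol",
    chrom                  = "Chromosome",
    pos                    = "Start_Position",
    ref_allele             = "Reference_Allele",
    alt_allele             = "Tumor_Seq_Allele2",
    variant_classification = "Variant_Classification",
    protein_change         = "HGVSp_Short",
    transcript_id          = "Transcript_ID"
  )
}

#' Parse an HGVS-short protein change
#'
#' @param x Character vector like `"p.G12C"`.
#' @return Data frame with `ref_aa`, `position`, `alt_aa`; `NA` rows where
#'   the string is not a simple substitution.
#' @export
parse_protein_change <- function(x) {
  m <- regmatches(x, regexec("^p\\.([A-Z])([0-9]+)([A-Z*])$", x))
  ref <- vapply(m, function(g) if (length(g) == 4L) g[2] else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g) == 4L) g[3] else NA_character_, "")
  alt <- vapply(m, function(g) if (length(g) == 4L) g[4] else NA_character_, "")
  data.frame(ref_aa = ref, position = as.integer(pos), alt_aa = alt,
             stringsAsFactors = FALSE)
}

normalize_variant_class <- function(x) {
  out <- ifelse(x %in% VARIANT_CLASSES, x,
                unname(MAF_CLASS_MAP[match(x, names(MAF_CLASS_MAP))]))
  out[is.na(out)] <- "other"
  out
}

#' Read a MAF-like mutation table
#'
#' Parses a tab-separated mutation annotation table into a validated
#' mutation data frame (one row per somatic mutation). Variant
#' classifications are normalized to
#' `missense/nonsense/frameshift/splice/silent/other`; silent records are
#' retained but flagged in the `is_silent` column.
#'
#' @param path Path to a (optionally gzipped) tab-separated file.
#' @param col_map Column mapping, see [maf_col_map()]. `sample_id`,
#'   `hugo_symbol` and `variant_classification` are mandatory columns;
#'   the rest are filled with `NA`/empty when absent from the header.
#' @return Data frame with columns `sample_id`, `hugo_symbol`, `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `variant_classification`,
#'   `protein_change`, `transcript_id`, `is_silent`.
#' @export
read_maf <- function(path, col_map = maf_col_map()) {
  df <- read_tsv(path, colClasses = "character")
  mandatory <- c("sample_id", "hugo_symbol", "variant_classification")
  for (f in mandatory) {
    if (!(col_map[[f]] %in% names(df))) {
      format_error("MAF file %s is missing mandatory column '%s'",
                   path, col_map[[f]])
    }
  }
  get_col <- function(field, default = NA_character_) {
    nm <- col_map[[field]]
    if (!is.null(nm) && nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  out <- data.frame(
    sample_id              = get_col("sample_id"),
    hugo_symbol            = get_col("hugo_symbol"),
    chrom                  = get_col("chrom", ""),
    pos                    = suppressWarnings(as.integer(get_col("pos", NA))),
    ref_allele             = get_col("ref_allele", ""),
    alt_allele             = get_col("alt_allele", ""),
    variant_classification = normalize_variant_class(
      get_col("variant_classification")),
    protein_change         = get_col("protein_change", ""),
    transcript_id          = get_col("transcript_id", ""),
    stringsAsFactors = FALSE
  )
  out$protein_change[is.na(out$protein_change)] <- ""
  out$transcript_id[is.na(out$transcript_id)] <- ""
  out$is_silent <- out$variant_classification == "silent"
  validate_mutations(out, path)
  out
}

validate_mutations <- function(df, path = "<mutations>") {
  bad <- which(!is.na(df$pos) & df$pos < 1L)
  if (length(bad)) {
    record_error("%s row %d: position %d < 1", path, bad[1], df$pos[bad[1]])
  }
  have_alleles <- nzchar(df$ref_allele) & nzchar(df$alt_allele)
  bad <- which(have_alleles & df$ref_allele == df$alt_allele)
  if (length(bad)) {
    record_error("%s row %d: ref_allele equals alt_allele ('%s')",
                 path, bad[1], df$ref_allele[bad[1]])
  }
  mis <- which(df$variant_classification == "missense")
  if (length(mis)) {
    pc <- parse_protein_change(df$protein_change[mis])
    bad <- which(is.na(pc$position) | pc$alt_aa == "*")
    if (length(bad)) {
      record_error("%s row %d: missense record with unparseable protein_change '%s'",
                   path, mis[bad[1]], df$protein_change[mis[bad[1]]])
    }
    bad <- which(pc$ref_aa == pc$alt_aa)
    if (length(bad)) {
      record_error("%s row %d: missense protein_change '%s' has ref_aa == alt_aa",
                   path, mis[bad[1]], df$protein_change[mis[bad[1]]])
    }
  }
  invisible(df)
}

#' Write a mutation data frame as a MAF-like table
#'
#' @param muts Mutation data frame as returned by [read_maf()].
#' @param path Output path (`.gz` supported).
#' @param col_map Column mapping, see [maf_col_map()].
#' @return `path`, invisibly.
#' @export
write_maf <- function(muts, path, col_map = maf_col_map()) {
  fields <- setdiff(names(col_map), character(0))
  out <- muts[, fields]
  names(out) <- unlist(col_map[fields])
  write_tsv(out, path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`.
#' Duplicate genes within a line are dropped with a warning; duplicate set
#' names across lines are an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (genes), with a `description`
#'   attribute carrying the second field per set.
#' @export
read_gmt <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) format_error("GMT file %s is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    format_error("GMT file %s line %d has fewer than 3 fields", path, short[1])
  }
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    format_error("GMT file %s contains duplicate set name '%s'",
                 path, nms[duplicated(nms)][1])
  }
  sets <- lapply(seq_along(parts), function(i) {
    genes <- parts[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate genes deduplicated", nms[i]),
              call. = FALSE)
      genes <- unique(genes)
    }
    if (!length(genes)) format_error("GMT set '%s' has no genes", nms[i])
    genes
  })
  names(sets) <- nms
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), nms)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  write_lines_any(lines, path)
}

#' Construct an expression matrix object
#'
#' Wraps a genes x samples matrix of linear-scale normalized expression
#' values (finite, non-negative, unique gene and sample identifiers) and
#' computes the per-gene z-score view used for ranking: `(x - mean) / sd`
#' with the sample standard deviation (ddof = 1). A constant gene has an
#' all-zero z-score row by definition.
#'
#' @param values Numeric matrix, rownames = gene symbols, colnames =
#'   sample ids.
#' @return Object of class `expr_matrix` with elements `values` and
#'   `zscores`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    format_error("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    format_error("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    format_error("duplicate gene identifier '%s' in expression matrix",
                 rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    format_error("duplicate sample identifier '%s' in expression matrix",
                 colnames(values)[duplicated(colnames(values))][1])
  }
  if (any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    format_error("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]])
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    format_error("negative expression value at gene '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]])
  }
  mu <- rowMeans(values)
  s <- apply(values, 1L, sd)           # sample SD, ddof = 1
  z <- (values - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  structure(list(values = values, zscores = z), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a genes x samples expression TSV
#'
#' First column holds gene symbols; remaining columns are samples with
#' linear-scale normalized values. See [expression_matrix()] for the
#' validation rules and the z-score view.
#'
#' @param path Path to the TSV (`.gz` supported).
#' @return An `expr_matrix` object.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) format_error("expression TSV %s has no sample columns", path)
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      format_error("non-numeric expression value '%s' at gene '%s', sample '%s'",
                   v[bad], genes[bad], names(vals)[j])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m)
}

#' Write an expression matrix as TSV
#'
#' @param expr An `expr_matrix` object (or bare numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else expr
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet; `X` is tolerated but flagged with a warning (such positions
#' are unusable for binding prediction). Duplicate identifiers and any
#' other letter are errors.
#'
#' @param path Path to a FASTA file (`.gz` supported).
#' @return Named character vector: transcript/protein id -> sequence.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    format_error("FASTA %s: duplicate identifier '%s'",
                 path, ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!(chars %in% c(AA20, "X")))
    if (length(bad)) {
      format_error("FASTA %s: illegal character '%s' in '%s' at position %d",
                   path, chars[bad[1]], ids[i], bad[1])
    }
    if (any(chars == "X")) {
      warning(sprintf("FASTA sequence '%s' contains ambiguous residue X", ids[i]),
              call. = FALSE)
    }
  }
  seqs
}

#' Write protein sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  write_lines_any(lines, path)
}

HLA_ALLELE_RE <- "^HLA-[ABC]\\*[0-9]{2}:[0-9]{2,3}$"

#' Read class-I HLA genotypes
#'
#' TSV with columns `sample_id`, `a1`, `a2`, `b1`, `b2`, `c1`, `c2`:
#' exactly six class-I alleles per sample in `HLA-A*02:01` notation
#' (homozygotes repeat the allele).
#'
#' @param path Path to the TSV.
#' @return Data frame with `sample_id` and the six allele columns.
#' @export
read_hla <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("sample_id", "a1", "a2", "b1", "b2", "c1", "c2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    format_error("HLA table %s missing column '%s'", path, miss[1])
  }
  for (col in need[-1]) {
    bad <- which(!grepl(HLA_ALLELE_RE, df[[col]]))
    if (length(bad)) {
      record_error("HLA table %s row %d: invalid allele '%s'",
                   path, bad[1], df[[col]][bad[1]])
    }
  }
  loci <- substr(unlist(df[c("a1", "a2")]), 5, 5)
  if (!all(loci == "A")) record_error("HLA table %s: a1/a2 must be HLA-A alleles", path)
  df[, need]
}

#' Read the clinical table
#'
#' TSV with mandatory columns `sample_id`, `os_months` (non-negative) and
#' `os_event` (0/1, 1 = death observed); optional label columns
#' (`smoking_pack_years`, `cluster_label`, `histology_label`,
#' `oncogene_status`) are carried through when present.
#'
#' @param path Path to the TSV.
#' @return Data frame of clinical records.
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) format_error("clinical table %s missing column '%s'", path, miss[1])
  if (any(df$os_months < 0, na.rm = TRUE)) {
    bad <- which(df$os_months < 0)[1]
    record_error("clinical table %s row %d: negative os_months", path, bad)
  }
  if (!all(df$os_event %in% c(0L, 1L))) {
    record_error("clinical table %s: os_event must be 0/1", path)
  }
  df
}
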