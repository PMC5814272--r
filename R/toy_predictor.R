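#' Deterministic toy MHC-binding predictor
#'
#' A stand-in for an external class-I binding predictor, used by the
#' synthetic cohort and the test-suite. Each supported allele carries a
#' packaged 9-position x 20-amino-acid weight table (`toy_pwm.tsv` under
#' `inst/extdata`); a peptide's score is the sum of per-position weights
#' and is mapped to the nanomolar scale through the decreasing function
#' `IC50 = 50000^(1 - score/9)`, so higher weight sums mean stronger
#' predicted binding (lower IC50). The mapping is fully deterministic:
#' identical input always yields identical output.
#'
#' @name toy_predictor
NULL

.pwm_cache <- new.env(parent = emptyenv())

toy_pwm <- function() {
  if (is.null(.pwm_cache$pwm)) {
    path <- system.file("extdata", "toy_pwm.tsv", package = "neoimmune",
                        mustWork = TRUE)
    df <- read_tsv(path)
    pwm <- split(df, df$allele)
    pwm <- lapply(pwm, function(d) {
      d <- d[order(d$position), ]
      m <- as.matrix(d[, AA20])
      rownames(m) <- NULL
      m
    })
    .pwm_cache$pwm <- pwm
  }
  .pwm_cache$pwm
}

#' Alleles supported by the toy predictor
#' @return Character vector of class-I allele names.
#' @export
toy_alleles <- function() names(toy_pwm())

#' Predict binding IC50 for peptide/allele pairs
#'
#' @param peptide Character vector of 9-mer peptides over the 20-letter
#'   amino-acid alphabet.
#' @param allele Character vector of allele names (recycled against
#'   `peptide`); must be among [toy_alleles()].
#' @return Numeric vector of IC50 values in nM (positive).
#' @export
#' @examples
#' toy_binding_predictor("ACDEFGHIK", "HLA-A*02:01")
toy_binding_predictor <- function(peptide, allele) {
  n <- max(length(peptide), length(allele))
  peptide <- rep_len(peptide, n)
  allele <- rep_len(allele, n)
  pwm <- toy_pwm()
  bad <- which(!(allele %in% names(pwm)))
  if (length(bad)) {
    data_error("toy predictor: unknown allele '%s'", allele[bad[1]])
  }
  if (any(nchar(peptide) != 9L)) {
    bad <- which(nchar(peptide) != 9L)[1]
    data_error("toy predictor: peptide '%s' has length %d, expected 9",
               peptide[bad], nchar(peptide[bad]))
  }
  chars <- matrix(unlist(strsplit(peptide, "")), nrow = 9L)
  idx <- match(chars, AA20)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    data_error("toy predictor: illegal residue '%s' in peptide '%s'",
               chars[bad], peptide[ceiling(bad / 9)])
  }
  idx <- matrix(idx, nrow = 9L)
  scores <- numeric(n)
  for (al in unique(allele)) {
    j <- which(allele == al)
    m <- pwm[[al]]
    # sum of w[position, residue] down each peptide column
    scores[j] <- colSums(matrix(m[cbind(rep(1:9, length(j)), as.vector(idx[, j]))],
                                nrow = 9L))
  }
  50000^(1 - scores / 9)
}
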