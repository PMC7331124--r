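#' Read SNP genotypes as allele counts
#'
#' Supports two text formats: a PLINK `.raw`-style table (whitespace
#' separated, header with `FID IID PAT MAT SEX PHENOTYPE` followed by one
#' column per SNP holding counts of the first allele) and VCF, where the
#' `GT` field is converted to counts of the reference allele. Any CSV whose
#' first column is `animal_id` and remaining columns are 0/1/2 counts is
#' also accepted.
#'
#' @param path file path (`.raw`, `.vcf`/`.vcf.gz`, or `.csv`).
#' @return A [genotype_matrix()] with animal-id rownames.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF genotypes requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")   # variants x samples
    # count REFERENCE alleles (the "first allele" of each site)
    counts <- t(apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_integer_)
      sum(strsplit(g, "[/|]")[[1]] == "0")
    }))
    if (anyNA(counts)) stop("missing genotypes are not supported")
    genotype_matrix(counts)
  } else if (grepl("\\.raw$", path)) {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE)
    meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(df))
    counts <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
    rownames(counts) <- as.character(df$IID)
    genotype_matrix(counts)
  } else {
    df <- read.csv(path, check.names = FALSE)
    if (names(df)[1] != "animal_id")
      stop("CSV genotypes need an animal_id first column")
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- as.character(df$animal_id)
    genotype_matrix(counts)
  }
}

#' Write variance components and GP^-1 eigenpairs as CSV
#'
#' Emits `<prefix>_covariances.csv` (long format: component, trait_i,
#' trait_j, value), `<prefix>_h2.csv` (per-trait heritability with SE) and,
#' when eigenpairs are supplied, `<prefix>_eigen.csv`.
#'
#' @param vc a [reml_estimate()] result.
#' @param prefix file-path prefix.
#' @param eigen optional [genetic_eigen()] result.
#' @export
write_variance_components <- function(vc, prefix, eigen = NULL) {
  stopifnot(inherits(vc, "variance_components"))
  Tn <- length(vc$h2)
  idx <- which(upper.tri(vc$G_cov, diag = TRUE), arr.ind = TRUE)
  long <- rbind(
    data.frame(component = "genetic", trait_i = idx[, 1], trait_j = idx[, 2],
               value = vc$G_cov[idx]),
    data.frame(component = "residual", trait_i = idx[, 1],
               trait_j = idx[, 2], value = vc$R_cov[idx]),
    data.frame(component = "phenotypic", trait_i = idx[, 1],
               trait_j = idx[, 2], value = vc$P_cov[idx]))
  write.csv(long, paste0(prefix, "_covariances.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(trait = seq_len(Tn), h2 = vc$h2, se = vc$h2_se,
                       boundary = vc$boundary),
            paste0(prefix, "_h2.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(eigen)) {
    ev <- data.frame(eigenvalue = rep(eigen$values,
                                      each = nrow(eigen$vectors)),
                     combination = rep(seq_along(eigen$values),
                                       each = nrow(eigen$vectors)),
                     trait = rep(seq_len(nrow(eigen$vectors)),
                                 length(eigen$values)),
                     loading = as.vector(eigen$vectors))
    write.csv(ev, paste0(prefix, "_eigen.csv"), row.names = FALSE,
              quote = FALSE)
  }
  invisible(prefix)
}

#' Write mixed-model solutions as CSV
#'
#' One file with the fixed-effect solutions (term, level, estimate, and the
#' number of observations behind each level) and one with the per-animal
#' breeding values.
#'
#' @param fit a [solve_mme()] result.
#' @param prefix file-path prefix.
#' @export
write_mme_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "mme_fit"))
  tm <- fit$design$term_map
  n_obs <- vapply(seq_len(nrow(tm)), function(i) {
    f <- tm$term[i]
    if (is.na(tm$level[i])) return(NA_real_)
    as.numeric(fit$level_counts[[f]][tm$level[i]])
  }, numeric(1))
  fx <- data.frame(term = tm$term, level = tm$level,
                   estimate = as.numeric(fit$b), n_obs = n_obs)
  write.csv(fx, paste0(prefix, "_fixed.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(animal_id = names(fit$u), ebv = as.numeric(fit$u)),
            paste0(prefix, "_ebv.csv"), row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
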