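## File formats (all tab-delimited text, missing values written "NA"):
##   marker map:  chrom  marker_id  genetic_pos_cM  bp_pos  freq_afr  freq_eur
##   matrices:    first column individual_id, remaining columns one per
##                marker (header = marker ids)
##   pedigree:    PLINK .fam-style, 6 columns, no header:
##                family individual father mother sex(1/2) phenotype(-9)
##   phenotypes:  individual_id  cac  age  sex
## Coordinates are 1-based bp; genetic positions are cM.

#' Write a simulated cohort to a directory of delimited text files
#'
#' @param cohort A `sim_cohort` (or any list with the same elements).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(map = file.path(dir, "map.tsv"),
             ancestry = file.path(dir, "ancestry.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             pedigree = file.path(dir, "pedigree.fam"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_marker_map(cohort$map, paths["map"])
  write_id_matrix(cohort$ancestry, paths["ancestry"])
  write_id_matrix(cohort$genotypes, paths["genotypes"])
  write_pedigree_fam(cohort$pedigree, paths["pedigree"])
  write_phenotypes(cohort$phenotypes, paths["phenotypes"])
  invisible(paths)
}

#' @rdname write_cohort
#' @param map,path Marker map and destination file.
#' @export
write_marker_map <- function(map, path) {
  out <- data.frame(chrom = map$chrom, marker_id = map$marker_id,
                    genetic_pos_cM = map$genetic_pos, bp_pos = map$bp_pos,
                    freq_afr = map$freq_afr, freq_eur = map$freq_eur)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_cohort
#' @param x Matrix with individual-id rownames and marker-id colnames.
#' @export
write_id_matrix <- function(x, path) {
  df <- data.frame(individual_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_cohort
#' @param pedigree Pedigree table.
#' @export
write_pedigree_fam <- function(pedigree, path) {
  out <- data.frame(
    pedigree$family_id, pedigree$individual_id,
    ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
    ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
    ifelse(pedigree$sex == "male", 1L, 2L),
    -9L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_cohort
#' @param phenotypes Phenotype table.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes[, c("individual_id", "cac", "age", "sex")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a marker map file
#'
#' @param path Tab-delimited file written by [write_marker_map()].
#' @return Marker map `data.frame` (columns `marker_id`, `chrom`, `bp_pos`,
#'   `genetic_pos`, `freq_afr`, `freq_eur`).
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "marker_id", "genetic_pos_cM", "bp_pos",
            "freq_afr", "freq_eur")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$marker_id))
    stop(sprintf("%s: duplicate marker ids", path))
  if (any(df$freq_afr < 0 | df$freq_afr > 1 |
          df$freq_eur < 0 | df$freq_eur > 1))
    stop(sprintf("%s: allele frequency outside [0, 1]", path))
  for (ch in unique(df$chrom)) {
    if (is.unsorted(df$bp_pos[df$chrom == ch]))
      stop(sprintf("%s: bp positions not non-decreasing on chromosome %s",
                   path, ch))
  }
  data.frame(marker_id = df$marker_id, chrom = df$chrom,
             bp_pos = df$bp_pos, genetic_pos = df$genetic_pos_cM,
             freq_afr = df$freq_afr, freq_eur = df$freq_eur,
             stringsAsFactors = FALSE)
}

## Shared reader for ancestry/genotype matrices with domain validation.
.read_id_matrix <- function(path, allowed, allow_na, what) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "individual_id")
    stop(sprintf("%s: first column must be 'individual_id'", path))
  ids <- df[[1]]
  x <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(x) <- "integer"
  rownames(x) <- ids
  bad <- which(!(x %in% allowed) & !(allow_na & is.na(x)))
  if (length(bad)) {
    r <- ((bad[1] - 1) %% nrow(x)) + 1
    c <- ((bad[1] - 1) %/% nrow(x)) + 1
    stop(sprintf(
      "%s: invalid %s value '%s' at row %d (%s), column %d (%s)",
      path, what, x[bad[1]], r, ids[r], c, colnames(x)[c]))
  }
  x
}

#' Read an ancestry matrix (African-allele counts)
#'
#' Values must be 0, 1 or 2; anything else is an error naming the offending
#' row and column.
#' @param path Tab-delimited file written by [write_id_matrix()].
#' @return Integer matrix with individual-id rownames.
#' @export
read_ancestry_matrix <- function(path) {
  .read_id_matrix(path, allowed = 0:2, allow_na = FALSE, what = "ancestry")
}

#' Read a genotype matrix (minor-allele counts, NA allowed)
#' @param path Tab-delimited file written by [write_id_matrix()].
#' @return Integer matrix with individual-id rownames.
#' @export
read_genotype_matrix <- function(path) {
  .read_id_matrix(path, allowed = 0:2, allow_na = TRUE, what = "genotype")
}

#' Read a PLINK .fam-style pedigree
#' @param path Six-column, headerless, whitespace-delimited file.
#' @return Pedigree `data.frame` (`family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`).
#' @export
read_pedigree_fam <- function(path) {
  df <- utils::read.table(path, stringsAsFactors = FALSE)
  if (ncol(df) < 5) stop(sprintf("%s: expected >= 5 columns", path))
  data.frame(family_id = as.character(df[[1]]),
             individual_id = as.character(df[[2]]),
             father_id = ifelse(df[[3]] == "0", NA, as.character(df[[3]])),
             mother_id = ifelse(df[[4]] == "0", NA, as.character(df[[4]])),
             sex = ifelse(df[[5]] == 1, "male", "female"),
             stringsAsFactors = FALSE)
}

#' Read a phenotype table
#' @param path Tab-delimited file with columns individual_id, cac, age, sex.
#' @return Phenotype `data.frame`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "cac", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  if (any(df$cac < 0, na.rm = TRUE))
    stop(sprintf("%s: negative CAC score", path))
  df
}

#' Read and cross-validate a cohort from files
#'
#' Loads the marker map, ancestry/genotype matrices, pedigree and phenotype
#' table, enforces the per-file invariants and checks id consistency:
#' ancestry and genotype individuals must appear in the pedigree; matrix
#' columns must match the map. Genotyped individuals absent from the
#' phenotype file are carried with missing phenotype (they fall to the
#' missing-phenotype exclusion downstream).
#'
#' @param dir Directory written by [write_cohort()], or `NULL` when the
#'   individual paths are given.
#' @param map,ancestry,genotypes,pedigree,phenotypes Individual file paths
#'   overriding the defaults under `dir`.
#' @return A list of class `sim_cohort` (without a truth record).
#' @export
read_cohort <- function(dir = NULL, map = NULL, ancestry = NULL,
                        genotypes = NULL, pedigree = NULL,
                        phenotypes = NULL) {
  p <- function(given, default) {
    if (!is.null(given)) given
    else if (!is.null(dir)) file.path(dir, default)
    else stop("supply 'dir' or all file paths")
  }
  mp <- read_marker_map(p(map, "map.tsv"))
  anc <- read_ancestry_matrix(p(ancestry, "ancestry.tsv"))
  gen <- read_genotype_matrix(p(genotypes, "genotypes.tsv"))
  ped <- read_pedigree_fam(p(pedigree, "pedigree.fam"))
  phe <- read_phenotypes(p(phenotypes, "phenotypes.tsv"))

  if (!identical(colnames(anc), mp$marker_id))
    stop("ancestry matrix columns do not match the marker map")
  if (!identical(colnames(gen), mp$marker_id))
    stop("genotype matrix columns do not match the marker map")
  if (!identical(rownames(anc), rownames(gen)))
    stop("ancestry and genotype matrices cover different individuals")
  missing_ped <- setdiff(rownames(anc), ped$individual_id)
  if (length(missing_ped))
    stop("individuals absent from pedigree: ",
         paste(utils::head(missing_ped, 5), collapse = ", "))
  extra_phe <- setdiff(phe$individual_id, rownames(anc))
  if (length(extra_phe))
    stop("phenotyped individuals without ancestry data: ",
         paste(utils::head(extra_phe, 5), collapse = ", "))
  absent <- setdiff(rownames(anc), phe$individual_id)
  if (length(absent)) {
    phe <- rbind(phe, data.frame(individual_id = absent, cac = NA_real_,
                                 age = NA_real_, sex = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  phe <- phe[match(rownames(anc), phe$individual_id), ]
  rownames(phe) <- NULL
  structure(list(ancestry = anc, genotypes = gen, pedigree = ped,
                 phenotypes = phe, map = mp, truth = NULL),
            class = "sim_cohort")
}
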