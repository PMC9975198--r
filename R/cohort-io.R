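#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile setNames p.adjust fisher.test cor aov
#'   rnbinom rbinom rnorm runif rexp qnbinom complete.cases pnorm qnorm pt
#'   glm binomial coef vcov kmeans sd var cor.test wilcox.test lm anova
#'   model.matrix pf na.omit rpois plogis pchisq model.frame model.response
#'   as.formula format.pval
#' @importFrom utils combn head read.delim write.table
NULL

# FACETS-style segment annotation vocabulary
SEGMENT_ANNOTATIONS <- c("DUP", "DUP-LOH", "HEMYZIG", "DEL", "NEUTRAL", "LOH-NEUTRAL")

TUMOR_TYPES <- c("non_metastatic", "aggressive", "metastatic_primary", "relapse", "metastasis")
GENOMIC_SUBTYPES <- c("pseudohypoxic", "kinase_signaling", "wnt_altered", "unknown")

variant_required_cols <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                           "consequence", "vaf")
variant_optional_cols <- c(gnomad_af = NA_real_, kg_af = NA_real_,
                           deleterious_votes = 0L, in_cosmic = FALSE,
                           artifact_flag = FALSE)

read_tsv_commented <- function(path) {
  as_tibble(read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                       check.names = FALSE))
}

validate_variant_table <- function(df, path = "<data>") {
  missing <- setdiff(variant_required_cols, names(df))
  if (length(missing) > 0) {
    stop("variant table ", path, " missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in names(variant_optional_cols)) {
    if (!nm %in% names(df)) df[[nm]] <- variant_optional_cols[[nm]]
  }
  bad <- which(df$pos < 1 | df$vaf < 0 | df$vaf > 1 | df$ref == df$alt)
  if (length(bad) > 0) {
    stop("malformed variant row(s) in ", path, " at line(s): ",
         paste(head(bad, 10), collapse = ", "),
         " (require pos >= 1, 0 <= vaf <= 1, ref != alt)", call. = FALSE)
  }
  df$in_cosmic <- as.logical(df$in_cosmic)
  df$artifact_flag <- as.logical(df$artifact_flag)
  df$deleterious_votes <- as.integer(df$deleterious_votes)
  unknown <- setdiff(unique(df$consequence), known_consequences())
  if (length(unknown) > 0) {
    warning("unknown consequence term(s) kept verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  as_tibble(df[, c(variant_required_cols, names(variant_optional_cols))])
}

#' Read a somatic variant table
#'
#' Reads per-sample somatic calls from either a MAF-like tab-delimited file or
#' a VCF 4.x file and returns one row per sample-variant with the columns the
#' curation ladder consumes. Coordinates are 1-based closed. Missing optional
#' annotations (population allele frequencies, predictor votes, COSMIC and
#' artifact flags) are set to missing/neutral values, never fabricated.
#'
#' For the `vcf` dialect annotations are taken from INFO keys `GENE`, `CSQ`
#' (consequence), `VAF`, `GNOMAD_AF`, `KG_AF`, `DVOTES`, `COSMIC`, `ARTIFACT`;
#' the sample id is the genotype column name (single-sample VCFs).
#'
#' @param path file path.
#' @param dialect `"maf_tsv"` (default) or `"vcf"`.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`, `vaf`, `gnomad_af`, `kg_af`, `deleterious_votes`,
#'   `in_cosmic`, `artifact_flag`.
#' @export
read_variant_table <- function(path, dialect = c("maf_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "maf_tsv") {
    df <- read_tsv_commented(path)
    return(validate_variant_table(df, path))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcf dialect requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info_field <- function(key) unname(vcfR::extract.info(v, element = key))
  sample_ids <- colnames(v@gt)[-1]
  sid <- if (length(sample_ids) >= 1) sample_ids[1] else
    sub("\\.vcf(\\.gz)?$", "", basename(path))
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  df <- tibble(
    sample_id = sid,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_field("GENE"),
    consequence = info_field("CSQ"),
    vaf = num_or_na(info_field("VAF")),
    gnomad_af = num_or_na(info_field("GNOMAD_AF")),
    kg_af = num_or_na(info_field("KG_AF")),
    deleterious_votes = {
      x <- suppressWarnings(as.integer(info_field("DVOTES")))
      ifelse(is.na(x), 0L, x)
    },
    in_cosmic = !is.na(info_field("COSMIC")) & info_field("COSMIC") %in% c("1", "TRUE", "true"),
    artifact_flag = !is.na(info_field("ARTIFACT")) & info_field("ARTIFACT") %in% c("1", "TRUE", "true")
  )
  validate_variant_table(df, path)
}

#' Read a copy-number segment table
#'
#' Reads a SEG-like tab-delimited table of FACETS-style segments. Coordinates
#' are 1-based closed. The `annotation` column must use the FACETS vocabulary
#' `DUP`, `DUP-LOH`, `HEMYZIG`, `DEL`, `NEUTRAL`, `LOH-NEUTRAL`.
#'
#' @param path file path to a TSV with columns `sample_id`, `chrom`, `start`,
#'   `end`, `total_cn`, `log_ratio`, `annotation` (optional `minor_cn`).
#' @return tibble of validated segments.
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_tsv_commented(path)
  required <- c("sample_id", "chrom", "start", "end", "total_cn", "log_ratio", "annotation")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("segment table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"minor_cn" %in% names(df)) df$minor_cn <- NA_integer_
  validate_segments(df)
}

validate_segments <- function(df) {
  df <- as_tibble(df)
  if (nrow(df) == 0) return(df)
  bad <- which(df$start > df$end)
  if (length(bad) > 0) {
    stop("segment start > end at row(s): ", paste(head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$annotation), SEGMENT_ANNOTATIONS)
  if (length(unknown) > 0) {
    stop("unknown segment annotation(s): ", paste(unknown, collapse = ", "),
         "; allowed values are: ", paste(SEGMENT_ANNOTATIONS, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a clinical table
#'
#' @param path TSV with at least `sample_id`, `patient_id`, `tumor_type`;
#'   recognised optional columns include `genomic_subtype`, `genotype`, `sex`,
#'   `age_at_surgery`, `ttp_days`, `progression_event`, `msi_score`,
#'   `krebs_germline`, `maml3_fusion`.
#' @return tibble of clinical records.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_tsv_commented(path)
  required <- c("sample_id", "patient_id", "tumor_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("clinical table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_clinical(df)
}

validate_clinical <- function(df) {
  df <- as_tibble(df)
  bad_type <- setdiff(unique(df$tumor_type), TUMOR_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown tumor_type value(s): ", paste(bad_type, collapse = ", "),
         "; allowed: ", paste(TUMOR_TYPES, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if ("ttp_days" %in% names(df) && any(df$ttp_days < 0, na.rm = TRUE)) {
    stop("ttp_days must be >= 0", call. = FALSE)
  }
  if ("msi_score" %in% names(df) && any(df$msi_score < 0, na.rm = TRUE)) {
    stop("msi_score must be >= 0 when present", call. = FALSE)
  }
  df
}

#' Read a genes-by-samples expression matrix
#'
#' Expects a TSV whose first column holds gene symbols and remaining columns
#' one sample each. Duplicate gene symbols are collapsed with
#' [collapse_genes()].
#'
#' @param path file path.
#' @param collapse collapse duplicated gene symbols (default TRUE).
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression_matrix <- function(path, collapse = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  if (any(mat < 0, na.rm = TRUE)) {
    warning("negative expression values present; raw counts expected to be >= 0",
            call. = FALSE)
  }
  if (collapse) mat <- collapse_genes(mat)
  mat
}

#' Collapse duplicated gene symbols
#'
#' For each duplicated symbol only the row with the maximal total expression
#' across samples is kept (ties broken by first occurrence, so the operation
#' is idempotent).
#'
#' @param mat genes-by-samples numeric matrix with symbol rownames.
#' @return matrix with unique rownames.
#' @export
collapse_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  totals <- rowSums(mat)
  ord <- order(rownames(mat), -totals)
  mat <- mat[ord, , drop = FALSE]
  mat[!duplicated(rownames(mat)), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path MSigDB-style GMT: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Bundled chromosome-arm coordinate table
#'
#' Returns the 1-based closed arm coordinates bundled with the package.
#' Boundaries are cytoband-derived centromere approximations (rounded to Mb);
#' a user-supplied table can replace them anywhere an `arm_table` argument is
#' accepted.
#'
#' @param build `"GRCh37"` or `"GRCh38"`.
#' @return tibble with columns `chrom`, `arm`, `start`, `end`.
#' @export
arm_table <- function(build = c("GRCh37", "GRCh38")) {
  build <- match.arg(build)
  path <- system.file("extdata", paste0("arms_", build, ".tsv"),
                      package = "ppglmetrisk")
  read_tsv_commented(path)
}

#' Assemble a cohort bundle
#'
#' Cross-references the omics tables against the clinical table and returns a
#' validated `ppgl_cohort` object. Every sample id appearing in a variant,
#' segment or expression table must exist in the clinical table; clinical-only
#' samples are retained and flagged in the availability report.
#'
#' @param clinical clinical tibble (required).
#' @param variants,segments optional tibbles as returned by the readers.
#' @param expression optional genes-by-samples matrix.
#' @param arm_table optional arm coordinate tibble; defaults to the bundled
#'   table for `build`.
#' @param build genome build, `"GRCh37"` (default) or `"GRCh38"`.
#' @return `ppgl_cohort`: a list with elements `clinical`, `variants`,
#'   `segments`, `expression`, `arm_table`, `build`, `availability`.
#' @export
assemble_bundle <- function(clinical, variants = NULL, segments = NULL,
                            expression = NULL, arm_table = NULL,
                            build = c("GRCh37", "GRCh38")) {
  build <- match.arg(build)
  clinical <- validate_clinical(clinical)
  if (is.null(arm_table)) arm_table <- ppglmetrisk::arm_table(build)
  known <- clinical$sample_id
  check_orphans <- function(ids, what) {
    orphan <- setdiff(unique(ids), known)
    if (length(orphan) > 0) {
      stop(what, " sample id(s) absent from clinical table: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(variants)) check_orphans(variants$sample_id, "variant")
  if (!is.null(segments)) check_orphans(segments$sample_id, "segment")
  if (!is.null(expression)) check_orphans(colnames(expression), "expression")
  availability <- tibble(
    sample_id = known,
    has_variants = if (is.null(variants)) FALSE else known %in% variants$sample_id,
    has_segments = if (is.null(segments)) FALSE else known %in% segments$sample_id,
    has_expression = if (is.null(expression)) FALSE else known %in% colnames(expression)
  )
  availability$no_omics <- !availability$has_variants &
    !availability$has_segments & !availability$has_expression
  structure(
    list(clinical = clinical, variants = variants, segments = segments,
         expression = expression, arm_table = as_tibble(arm_table),
         build = build, availability = availability),
    class = "ppgl_cohort")
}

#' @export
print.ppgl_cohort <- function(x, ...) {
  cat("<ppgl_cohort> ", nrow(x$clinical), " samples (", x$build, ")\n", sep = "")
  cat("  variants:   ", if (is.null(x$variants)) 0 else nrow(x$variants), " rows\n", sep = "")
  cat("  segments:   ", if (is.null(x$segments)) 0 else nrow(x$segments), " rows\n", sep = "")
  cat("  expression: ", if (is.null(x$expression)) "absent" else
    paste(nrow(x$expression), "genes x", ncol(x$expression), "samples"), "\n", sep = "")
  cat("  no omics:   ", sum(x$availability$no_omics), " sample(s)\n", sep = "")
  invisible(x)
}

#' Write a table as TSV with a metadata header
#'
#' All writers emit a header line plus '#'-prefixed metadata; coordinates in
#' written tables are 1-based closed.
#'
#' @param df data frame.
#' @param path output path.
#' @param meta character vector of metadata lines (written '#'-prefixed).
#' @export
write_table_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta) > 0) writeLines(paste0("# ", meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
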