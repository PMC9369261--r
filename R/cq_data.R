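#' Default study design: nine mouse brain regions, two genotypes
#'
#' The factor levels of the study layout: nine anatomical brain regions and
#' the wild-type (WT) versus Prader-Willi critical-region deletion (PWScr)
#' genotypes. Used as the default `design` everywhere a Cq table is read or
#' simulated.
#'
#' @return A list with character vectors `regions` and `genotypes`.
#' @export
#' @examples
#' brain_design()$regions
brain_design <- function() {
  list(
    regions = c(
      "olfactory bulb", "isocortex", "hippocampus", "thalamus",
      "hypothalamus", "midbrain", "cerebellum", "pons", "medulla"
    ),
    genotypes = c("WT", "PWScr")
  )
}

#' Construct a Cq table
#'
#' A `cq_table` holds a genes x samples matrix of crossing-point (Cq) values
#' together with per-sample annotations. Cq values are PCR cycles (typically
#' 10-40); `NA` marks a non-detect. Columns of `cq` correspond to rows of
#' `samples`.
#'
#' @param cq Numeric matrix, genes in rows (rownames are the unique gene
#'   symbols), samples in columns.
#' @param samples `data.frame` with columns `sample_id`, `region`,
#'   `genotype`, `bio_rep`, `tech_rep`; one row per column of `cq`.
#' @param design List with `regions` and `genotypes` giving the admissible
#'   factor levels; defaults to the levels observed in `samples`.
#' @return An object of class `cq_table`: a list with elements `genes`,
#'   `samples`, `cq` and attribute `design`.
#' @export
cq_table <- function(cq, samples, design = NULL) {
  cq <- as.matrix(cq)
  storage.mode(cq) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(design)) {
    design <- list(
      regions = unique(as.character(samples$region)),
      genotypes = unique(as.character(samples$genotype))
    )
  }
  x <- structure(
    list(genes = rownames(cq), samples = samples, cq = cq),
    design = design,
    class = "cq_table"
  )
  validate_cq_table(x)
  x
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf(
    "<%s> %d genes x %d samples (%d region(s), %d genotype(s))\n",
    class(x)[1], length(x$genes), nrow(x$samples),
    length(unique(x$samples$region)), length(unique(x$samples$genotype))
  ))
  invisible(x)
}

#' Validate a Cq table
#'
#' Checks the structural invariants: matching dimensions, unique gene
#' symbols, finite non-negative Cq (or `NA`), annotation columns present,
#' factor levels drawn from the declared design, and uniqueness of
#' (region, genotype, bio_rep, tech_rep).
#'
#' @param x A `cq_table`.
#' @return `x`, invisibly. Errors describe the first violated invariant.
#' @export
validate_cq_table <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  req <- c("sample_id", "region", "genotype", "bio_rep", "tech_rep")
  missing_cols <- setdiff(req, names(x$samples))
  if (length(missing_cols)) {
    stop("sample annotations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(rownames(x$cq))) stop("cq matrix must have gene symbols as rownames")
  if (anyDuplicated(x$genes)) {
    stop("duplicate gene symbols: ",
         paste(unique(x$genes[duplicated(x$genes)]), collapse = ", "))
  }
  if (!identical(rownames(x$cq), x$genes)) stop("gene list does not match cq rownames")
  if (ncol(x$cq) != nrow(x$samples)) {
    stop(sprintf("cq has %d columns but %d sample annotations", ncol(x$cq), nrow(x$samples)))
  }
  vals <- x$cq[!is.na(x$cq)]
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all non-missing Cq values must be finite and >= 0")
  }
  design <- attr(x, "design")
  bad_r <- setdiff(unique(as.character(x$samples$region)), design$regions)
  if (length(bad_r)) {
    stop("unknown region(s): ", paste(bad_r, collapse = ", "),
         "; valid: ", paste(design$regions, collapse = ", "))
  }
  bad_g <- setdiff(unique(as.character(x$samples$genotype)), design$genotypes)
  if (length(bad_g)) {
    stop("unknown genotype(s): ", paste(bad_g, collapse = ", "),
         "; valid: ", paste(design$genotypes, collapse = ", "))
  }
  if (any(x$samples$bio_rep < 1) || any(x$samples$tech_rep < 1)) {
    stop("bio_rep and tech_rep must be positive integers")
  }
  key <- interaction(x$samples$region, x$samples$genotype,
                     x$samples$bio_rep, x$samples$tech_rep, drop = TRUE)
  if (anyDuplicated(key)) {
    dup <- as.character(key[duplicated(key)])
    stop("duplicate (region, genotype, bio_rep, tech_rep) sample(s): ",
         paste(unique(dup), collapse = ", "))
  }
  invisible(x)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a Cq table from delimited text
#'
#' Canonical input is long format with header columns `sample_id`, `gene`,
#' `cq`, `region`, `genotype`, `bio_rep`, `tech_rep` (comma- or tab-delimited,
#' auto-detected). Wide format (one column per gene next to the annotation
#' columns) is accepted with `wide = TRUE`. Empty or `NA` Cq cells become
#' missing values; any other non-numeric Cq is a parse error reported with
#' its line number.
#'
#' @param path Path to the delimited text file.
#' @param design Admissible factor levels (see [brain_design()]).
#' @param wide Logical; `TRUE` for gene-per-column layout.
#' @return A validated [cq_table()].
#' @export
read_cq_table <- function(path, design = brain_design(), wide = FALSE) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  sep <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", encoding = "UTF-8")
  ann_cols <- c("sample_id", "region", "genotype", "bio_rep", "tech_rep")
  if (wide) {
    miss <- setdiff(ann_cols, names(raw))
    if (length(miss)) stop("wide input lacks column(s): ", paste(miss, collapse = ", "))
    gene_cols <- setdiff(names(raw), ann_cols)
    if (!length(gene_cols)) stop("wide input has no gene columns")
    long <- do.call(rbind, lapply(gene_cols, function(g) {
      data.frame(raw[ann_cols], gene = g, cq = raw[[g]],
                 stringsAsFactors = FALSE)
    }))
    raw <- long
  } else {
    miss <- setdiff(c(ann_cols, "gene", "cq"), names(raw))
    if (length(miss)) stop("long input lacks column(s): ", paste(miss, collapse = ", "))
  }
  cq_chr <- trimws(raw$cq)
  is_missing <- is.na(cq_chr) | cq_chr == "" | toupper(cq_chr) == "NA"
  cq_num <- suppressWarnings(as.numeric(cq_chr))
  bad <- which(!is_missing & is.na(cq_num))
  if (length(bad)) {
    stop(sprintf("non-numeric Cq value '%s' at data line %d", cq_chr[bad[1]], bad[1]))
  }
  cq_num[is_missing] <- NA_real_
  for (col in c("bio_rep", "tech_rep")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-integer %s '%s' at data line %d", col, raw[[col]][bad[1]], bad[1]))
    }
    raw[[col]] <- v
  }

  pair <- paste(raw$gene, raw$sample_id, sep = " / ")
  if (anyDuplicated(pair)) {
    stop("duplicate (gene, sample) pair(s): ",
         paste(unique(pair[duplicated(pair)]), collapse = "; "))
  }
  genes <- unique(raw$gene)
  sample_ids <- unique(raw$sample_id)
  ann <- raw[!duplicated(raw$sample_id), ann_cols]
  rownames(ann) <- NULL
  # annotations must be consistent within a sample_id
  chk <- unique(raw[, ann_cols])
  if (anyDuplicated(chk$sample_id)) {
    stop("inconsistent annotations for sample_id: ",
         paste(unique(chk$sample_id[duplicated(chk$sample_id)]), collapse = ", "))
  }
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_ids),
              dimnames = list(genes, sample_ids))
  m[cbind(match(raw$gene, genes), match(raw$sample_id, sample_ids))] <- cq_num
  cq_table(m, ann, design = design)
}

#' Write a Cq table as long-format TSV
#'
#' Values are written with enough digits to round-trip through
#' [read_cq_table()] well beyond six significant digits.
#'
#' @param x A `cq_table` or `collapsed_cq_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(x, path) {
  stopifnot(inherits(x, "cq_table"))
  s <- x$samples
  tech <- if ("tech_rep" %in% names(s)) s$tech_rep else 1L
  long <- data.frame(
    sample_id = rep(s$sample_id, each = length(x$genes)),
    gene = rep(x$genes, times = nrow(s)),
    cq = ifelse(is.na(c(x$cq)), "NA", sprintf("%.12g", c(x$cq))),
    region = rep(s$region, each = length(x$genes)),
    genotype = rep(s$genotype, each = length(x$genes)),
    bio_rep = rep(s$bio_rep, each = length(x$genes)),
    tech_rep = rep(tech, each = length(x$genes)),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average technical replicates into one column per biological replicate
#'
#' Each (region, genotype, bio_rep) cell's technical replicates are collapsed
#' by their arithmetic mean on the Cq scale (standard qPCR practice); a cell
#' is missing only if all its technical replicates are missing. The
#' per-cell SD of the technical replicates is kept as `tech_spread`; cells
#' whose spread exceeds `spread_warn` cycles are reported in a warning and
#' listed in the `flagged` attribute, but never removed.
#'
#' Collapsing an already-collapsed table is the identity.
#'
#' @param x A [cq_table()].
#' @param spread_warn Technical-spread threshold in cycles (default 0.5).
#' @return A `collapsed_cq_table`: a `cq_table` with one column per
#'   biological replicate, a `tech_spread` matrix, an `n_tech` matrix of
#'   contributing replicate counts, and attribute `flagged`.
#' @export
collapse_technical_replicates <- function(x, spread_warn = 0.5) {
  stopifnot(inherits(x, "cq_table"))
  if (inherits(x, "collapsed_cq_table")) return(x)
  s <- x$samples
  key <- paste(s$region, s$genotype, s$bio_rep, sep = "\r")
  units <- unique(key)
  idx <- split(seq_len(nrow(s)), factor(key, levels = units))
  n_units <- length(units)
  g <- length(x$genes)
  cq <- matrix(NA_real_, g, n_units)
  spread <- matrix(NA_real_, g, n_units)
  ntech <- matrix(0L, g, n_units)
  ann <- s[vapply(idx, `[`, integer(1), 1L), c("region", "genotype", "bio_rep")]
  ann$sample_id <- paste(gsub("[^[:alnum:]]+", "_", ann$region),
                         ann$genotype, ann$bio_rep, sep = "_")
  ann$tech_rep <- 1L
  ann <- ann[c("sample_id", "region", "genotype", "bio_rep", "tech_rep")]
  rownames(ann) <- NULL
  for (j in seq_len(n_units)) {
    block <- x$cq[, idx[[j]], drop = FALSE]
    k <- rowSums(!is.na(block))
    cq[, j] <- ifelse(k > 0, rowMeans(block, na.rm = TRUE), NA_real_)
    ntech[, j] <- k
    spread[, j] <- apply(block, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2) stats::sd(v) else NA_real_
    })
  }
  dimnames(cq) <- list(x$genes, ann$sample_id)
  dimnames(spread) <- dimnames(cq)
  dimnames(ntech) <- dimnames(cq)
  flag_idx <- which(!is.na(spread) & spread > spread_warn, arr.ind = TRUE)
  flagged <- data.frame(
    gene = x$genes[flag_idx[, 1]],
    sample_id = ann$sample_id[flag_idx[, 2]],
    tech_spread = spread[flag_idx],
    stringsAsFactors = FALSE
  )
  out <- cq_table(cq, ann, design = attr(x, "design"))
  out$tech_spread <- spread
  out$n_tech <- ntech
  attr(out, "flagged") <- flagged
  class(out) <- c("collapsed_cq_table", class(out))
  if (nrow(flagged)) {
    warning(sprintf(
      "%d cell(s) with technical spread > %.3g cycles, e.g. %s in %s (SD %.3g)",
      nrow(flagged), spread_warn, flagged$gene[1], flagged$sample_id[1],
      flagged$tech_spread[1]
    ))
  }
  out
}

#' Subset a Cq table by condition and/or genes
#'
#' Filters columns to the requested region and/or genotype levels and rows to
#' the requested genes, preserving the original orderings. Requested levels
#' must exist in the table; an empty selection is an error.
#'
#' @param x A `cq_table` or `collapsed_cq_table`.
#' @param region,genotype Optional character vectors of levels to keep.
#' @param genes Optional character vector of gene symbols to keep.
#' @return The sub-table, same class as `x`.
#' @export
subset_condition <- function(x, region = NULL, genotype = NULL, genes = NULL) {
  stopifnot(inherits(x, "cq_table"))
  keep <- rep(TRUE, nrow(x$samples))
  if (!is.null(region)) {
    bad <- setdiff(region, unique(x$samples$region))
    if (length(bad)) {
      stop("region(s) not in table: ", paste(bad, collapse = ", "),
           "; available: ", paste(unique(x$samples$region), collapse = ", "))
    }
    keep <- keep & x$samples$region %in% region
  }
  if (!is.null(genotype)) {
    bad <- setdiff(genotype, unique(x$samples$genotype))
    if (length(bad)) {
      stop("genotype(s) not in table: ", paste(bad, collapse = ", "),
           "; available: ", paste(unique(x$samples$genotype), collapse = ", "))
    }
    keep <- keep & x$samples$genotype %in% genotype
  }
  row_keep <- rep(TRUE, length(x$genes))
  if (!is.null(genes)) {
    bad <- setdiff(genes, x$genes)
    if (length(bad)) stop("gene(s) not in table: ", paste(bad, collapse = ", "))
    row_keep <- x$genes %in% genes
  }
  if (!any(keep) || !any(row_keep)) stop("empty selection")
  out <- x
  out$genes <- x$genes[row_keep]
  out$samples <- x$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out$cq <- x$cq[row_keep, keep, drop = FALSE]
  if (!is.null(x$tech_spread)) {
    out$tech_spread <- x$tech_spread[row_keep, keep, drop = FALSE]
    out$n_tech <- x$n_tech[row_keep, keep, drop = FALSE]
  }
  validate_cq_table(out)
  out
}
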