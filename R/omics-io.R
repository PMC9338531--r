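#' Omics abundance matrix
#'
#' Light container for one omics layer: a genes x samples numeric matrix with
#' a layer tag and a flag recording whether values are on the log2 scale.
#'
#' @param values numeric matrix, rownames = gene IDs, colnames = sample IDs.
#' @param layer `"protein"` or `"mrna"`.
#' @param log2 logical; TRUE once [transform_abundance] has been applied.
#' @return object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, layer = c("protein", "mrna"), log2 = FALSE) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("omics_matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene IDs: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values))) stopf("duplicate sample IDs")
  if (layer == "mrna" && !log2 && any(values < 0, na.rm = TRUE))
    stopf("mRNA abundances must be nonnegative before log transform")
  structure(list(values = values, layer = layer, log2 = log2),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s%s]: %d genes x %d samples, %.1f%% missing\n",
              x$layer, if (x$log2) ", log2" else "",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read an abundance matrix from TSV
#'
#' First column = gene ID, remaining columns = samples. Blank or `NA` cells
#' become missing values; duplicate gene IDs, ragged rows and non-numeric
#' cells are rejected.
#'
#' @param path TSV file with a header line.
#' @param layer `"protein"` or `"mrna"`.
#' @return an [omics_matrix] on the raw abundance scale.
#' @export
read_omics_matrix <- function(path, layer = c("protein", "mrna")) {
  layer <- match.arg(layer)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), fill = FALSE)
  if (ncol(df) < 2) stopf("%s: need a gene ID column plus >= 1 sample", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stopf("duplicate gene ID in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[-1])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-numeric cell in %s at gene '%s', sample '%s': '%s'",
          path, ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]],
          vals[bad[1, 1], bad[1, 2]])
  dimnames(num) <- list(ids, colnames(df)[-1])
  omics_matrix(num, layer)
}

#' Log-transform an abundance matrix
#'
#' Proteins: log2(abundance); transcripts: log2(FPKM + 1).
#'
#' @param m an [omics_matrix] on the raw scale.
#' @return the matrix on the log2 scale (`log2 = TRUE`).
#' @export
transform_abundance <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$log2) return(m)
  v <- if (m$layer == "mrna") log2(m$values + 1) else log2(m$values)
  omics_matrix(v, m$layer, log2 = TRUE)
}

#' Remove low-abundance features
#'
#' Drops features whose median abundance (missing values ignored) falls below
#' the threshold. By default transcripts use median FPKM < 1 and proteins the
#' lowest decile of median abundance; both are conventional cuts, recorded on
#' the result.
#'
#' @param m an [omics_matrix] on the raw scale.
#' @param min_threshold abundance cutoff; `NULL` picks the layer default.
#' @return filtered [omics_matrix] with attribute `"threshold"`.
#' @export
filter_low_abundance <- function(m, min_threshold = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  med <- apply(m$values, 1, stats::median, na.rm = TRUE)
  if (is.null(min_threshold)) {
    min_threshold <- if (m$layer == "mrna") 1 else
      unname(stats::quantile(med, 0.1, na.rm = TRUE))
  }
  stopifnot(min_threshold >= 0)
  keep <- !is.na(med) & med >= min_threshold
  if (!any(keep)) stopf("filter_low_abundance removed every feature")
  out <- omics_matrix(m$values[keep, , drop = FALSE], m$layer, m$log2)
  attr(out, "threshold") <- min_threshold
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Missingness filter and K-nearest-neighbour imputation
#'
#' Features missing in more than `max_missing_frac` of samples are removed;
#' remaining missing cells are imputed by the mean of the `k_neighbors`
#' nearest samples (Euclidean distance on jointly observed features, log2
#' scale) that observe the feature. The output contains no missing values and
#' the operation is idempotent on its own output.
#'
#' @param m an [omics_matrix] (log2 scale recommended).
#' @param max_missing_frac maximum tolerated per-feature missing fraction.
#' @param k_neighbors neighbours used for imputation (< number of samples).
#' @return imputed [omics_matrix].
#' @export
filter_and_impute <- function(m, max_missing_frac = 0.2, k_neighbors = 10) {
  stopifnot(inherits(m, "omics_matrix"),
            max_missing_frac >= 0, max_missing_frac <= 1, k_neighbors >= 1)
  v <- m$values
  S <- ncol(v)
  if (k_neighbors >= S)
    stopf("k_neighbors (%d) must be < number of samples (%d)", k_neighbors, S)
  if (any(colSums(!is.na(v)) == 0))
    stopf("sample with zero observed features")
  keep <- rowMeans(is.na(v)) <= max_missing_frac
  v <- v[keep, , drop = FALSE]
  if (anyNA(v)) {
    # mean squared difference over jointly observed features
    d2 <- matrix(Inf, S, S)
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      ok <- !is.na(v[, i]) & !is.na(v[, j])
      if (any(ok)) d2[i, j] <- d2[j, i] <- mean((v[ok, i] - v[ok, j])^2)
    }
    miss <- which(is.na(v), arr.ind = TRUE)
    for (r in seq_len(nrow(miss))) {
      g <- miss[r, 1]; j <- miss[r, 2]
      cand <- setdiff(which(!is.na(v[g, ])), j)
      cand <- cand[order(d2[j, cand])]
      nb <- cand[seq_len(min(k_neighbors, length(cand)))]
      v[g, j] <- mean(v[g, nb])
    }
  }
  out <- omics_matrix(v, m$layer, m$log2)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Paired proteotranscriptomic cohort
#'
#' Matched protein and mRNA matrices restricted to shared genes and samples,
#' plus per-sample metadata.
#'
#' @param protein,mrna log2-scale [omics_matrix] objects (or bare matrices).
#' @param meta data.frame with a `sample` column covering the shared samples.
#' @return object of class `paired_cohort` with elements `protein`, `mrna`
#'   (bare matrices over identical dimnames), `meta`, and drop counts in
#'   attributes.
#' @export
build_paired_cohort <- function(protein, mrna, meta) {
  pv <- if (inherits(protein, "omics_matrix")) protein$values else protein
  mv <- if (inherits(mrna, "omics_matrix")) mrna$values else mrna
  genes <- intersect(rownames(pv), rownames(mv))
  samples <- intersect(colnames(pv), colnames(mv))
  if (!length(genes)) stopf("no shared genes between layers")
  if (!length(samples)) stopf("no shared samples between layers")
  if (!all(samples %in% meta$sample))
    stopf("metadata missing for samples: %s",
          paste(setdiff(samples, meta$sample), collapse = ", "))
  out <- paired_cohort_obj(pv[genes, samples, drop = FALSE],
                           mv[genes, samples, drop = FALSE],
                           meta[match(samples, meta$sample), , drop = FALSE])
  attr(out, "n_dropped_genes") <-
    length(union(rownames(pv), rownames(mv))) - length(genes)
  attr(out, "n_dropped_samples") <-
    length(union(colnames(pv), colnames(mv))) - length(samples)
  out
}

paired_cohort_obj <- function(protein, mrna, meta) {
  stopifnot(identical(dimnames(protein), dimnames(mrna)),
            nrow(protein) > 0)
  structure(list(protein = protein, mrna = mrna, meta = meta,
                 genes = rownames(protein), samples = colnames(protein)),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired_cohort: %d protein-mRNA pairs x %d samples\n",
              length(x$genes), length(x$samples)))
  print(table(x$meta$group))
  invisible(x)
}

splice_event_table_obj <- function(info, psi, groups) {
  stopifnot(nrow(info) == nrow(psi),
            identical(info$event_id, rownames(psi) %||% character(0)),
            all(colnames(psi) %in% names(groups)))
  if (any(psi < 0 | psi > 1, na.rm = TRUE))
    stopf("IncLevel outside [0, 1]")
  if (anyDuplicated(paste(info$type, info$event_id)))
    stopf("duplicate event IDs within a type")
  structure(list(info = info, psi = psi, groups = groups[colnames(psi)]),
            class = "splice_event_table")
}

#' @export
print.splice_event_table <- function(x, ...) {
  cat(sprintf("splice_event_table: %d events (%s) x %d samples\n",
              nrow(x$info),
              paste(sprintf("%s:%d", names(table(x$info$type)),
                            table(x$info$type)), collapse = " "),
              ncol(x$psi)))
  invisible(x)
}

#' Read an rMATS junction-count table
#'
#' Parses the JC dialect (columns `ID`, `GeneID`, `geneSymbol`, `IncLevel1`,
#' `IncLevel2`, `IncLevelDifference`, `PValue`, `FDR`); per-sample inclusion
#' levels come from the comma-separated `IncLevel1`/`IncLevel2` lists (`NA`
#' entries allowed), with group 1 taken as tumor and group 2 as control.
#'
#' @param path table file.
#' @param ase_type one of `"A3"`, `"A5"`, `"MX"`, `"RI"`, `"SE"`.
#' @param sample_names optional sample IDs, group-1 samples first.
#' @return a `splice_event_table`; the file's `IncLevelDifference`, `PValue`
#'   and `FDR` columns are kept in `$info`.
#' @export
read_rmats_table <- function(path, ase_type, sample_names = NULL) {
  stopifnot(ase_type %in% ase_types)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("ID", "GeneID", "geneSymbol", "IncLevel1", "IncLevel2",
            "IncLevelDifference", "PValue", "FDR")
  if (!all(need %in% colnames(df)))
    stopf("%s: missing columns %s", path,
          paste(setdiff(need, colnames(df)), collapse = ", "))
  parse_list <- function(s, row) {
    tok <- strsplit(s, ",", fixed = TRUE)[[1]]
    suppressWarnings(v <- as.numeric(tok))
    if (any(is.na(v) & tok != "NA"))
      stopf("%s: malformed IncLevel list in event '%s'", path, row)
    v
  }
  if (nrow(df) == 0) {
    sample_names <- sample_names %||% character(0)
    psi <- matrix(numeric(0), 0, length(sample_names),
                  dimnames = list(character(0), sample_names))
    info <- data.frame(event_id = character(0), type = character(0),
                       gene = character(0),
                       IncLevelDifference = numeric(0), PValue = numeric(0),
                       FDR = numeric(0), stringsAsFactors = FALSE)
    return(splice_event_table_obj(
      info, psi, stats::setNames(rep("tumor", length(sample_names)),
                                 sample_names)))
  }
  l1 <- lapply(seq_len(nrow(df)),
               function(i) parse_list(df$IncLevel1[i], df$ID[i]))
  l2 <- lapply(seq_len(nrow(df)),
               function(i) parse_list(df$IncLevel2[i], df$ID[i]))
  n1 <- unique(lengths(l1)); n2 <- unique(lengths(l2))
  if (length(n1) != 1 || length(n2) != 1)
    stopf("%s: inconsistent IncLevel list lengths", path)
  psi <- cbind(do.call(rbind, l1), do.call(rbind, l2))
  if (is.null(sample_names))
    sample_names <- c(sprintf("grp1_%02d", seq_len(n1)),
                      sprintf("grp2_%02d", seq_len(n2)))
  if (length(sample_names) != n1 + n2)
    stopf("%s: expected %d sample names, got %d", path, n1 + n2,
          length(sample_names))
  dimnames(psi) <- list(df$ID, sample_names)
  info <- data.frame(event_id = df$ID, type = ase_type, gene = df$geneSymbol,
                     IncLevelDifference = as.numeric(df$IncLevelDifference),
                     PValue = as.numeric(df$PValue),
                     FDR = as.numeric(df$FDR),
                     stringsAsFactors = FALSE)
  groups <- stats::setNames(rep(c("tumor", "control"), c(n1, n2)),
                            sample_names)
  splice_event_table_obj(info, psi, groups)
}

#' Combine per-type splice-event tables over the same samples
#'
#' @param fragments list of `splice_event_table` objects sharing sample IDs.
#' @return one `splice_event_table`.
#' @export
combine_event_tables <- function(fragments) {
  stopifnot(length(fragments) >= 1)
  cols <- colnames(fragments[[1]]$psi)
  info <- do.call(rbind, lapply(fragments, function(f) {
    f$info[, c("event_id", "type", "gene")]
  }))
  psi <- do.call(rbind, lapply(fragments,
                               function(f) f$psi[, cols, drop = FALSE]))
  rownames(info) <- NULL
  splice_event_table_obj(info, psi, fragments[[1]]$groups)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then members. Set names must be
#' unique and sets nonempty.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set names: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0))
    stopf("empty gene set: %s", paste(nm[lengths(sets) == 0], collapse = ", "))
  stats::setNames(sets, nm)
}

#' Read a splicing-factor list (one gene symbol per line)
#'
#' Duplicates are removed with a warning reporting how many.
#'
#' @param path text file.
#' @return character vector of unique gene symbols.
#' @export
read_sf_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x)]
  ndup <- sum(duplicated(x))
  if (ndup > 0) warnf("read_sf_list: removed %d duplicate entries", ndup)
  unique(x)
}
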