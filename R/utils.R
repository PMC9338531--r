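logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

ase_types <- c("A3", "A5", "MX", "RI", "SE")
group_levels <- c("normal", "inflammation", "tumor")
endpoint_names <- c("PFS", "OS", "RFS", "LRFS", "DRFS")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
as_group2 <- function(groups) {
  # collapse to tumor vs control; controls = normal + inflammation (IOI/RLH)
  factor(ifelse(groups == "tumor", "tumor", "control"),
         levels = c("control", "tumor"))
}

# Row-wise Welch t-tests on two matrices with matching rows.
# Returns delta (mean(a) - mean(b)), t, df, p. NAs allowed.
row_welch <- function(a, b) {
  na_ <- rowSums(!is.na(a)); nb_ <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na_ - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb_ - 1, 1)
  se2 <- va / na_ + vb / nb_
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_)^2 / pmax(na_ - 1, 1) + (vb / nb_)^2 / pmax(nb_ - 1, 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: zero variance in both groups
  degen <- se2 == 0 | !is.finite(tt)
  tt[degen] <- 0
  p[degen] <- 1
  data.frame(delta = ma - mb, t = tt, df = df, p = p,
             row.names = rownames(a))
}

# deterministic table writer used for all exports (fixed format => identical
# bytes for identical inputs)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}
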