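# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (double loops, direct counting) and share
# no code with the package implementations they check.

RES <- load_resources()

ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# brute-force skip-dipeptide enumerator: walk every index pair i < j
asdc_oracle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- numeric(400)
  names(out) <- paste0("asdc.", as.vector(t(outer(ALPHA, ALPHA, paste0))))
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      key <- paste0("asdc.", chars[i], chars[j])
      out[key] <- out[key] + 1
    }
  }
  out / (L * (L - 1) / 2)
}

# direct metric computation from prediction vectors, no confusion object
metrics_oracle <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  acc <- (tp + tn) / length(pred)
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  f1 <- if (pre + sn > 0) 2 * pre * sn / (pre + sn) else 0
  c(ACC = acc, MCC = mcc, Sn = sn, Sp = sp, Pre = pre, F1 = f1)
}

# AUC by counting concordant positive/negative score pairs (ties half)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

write_tmp_fasta <- function(ids, seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "peps.fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

toy_separable <- function(n = 40, seed = 1) {
  # two Gaussian blobs far apart in 2-D, alternating labels
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- cbind(stats::rnorm(n, mean = 6 * y), stats::rnorm(n, mean = -6 * y))
  })
  colnames(x) <- c("f1", "f2")
  list(x = x, y = y)
}
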