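# Classification metrics. The positive class is "cancer" throughout.

# Mann-Whitney / rank formulation of the ROC AUC; ties handled by midranks.
auc_score <- function(scores, labels, positive = POSITIVE_CLASS) {
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

confusion_metrics <- function(truth, predicted, positive = POSITIVE_CLASS) {
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / (tp + fn + tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(acc = acc, sens = sens, spec = spec, f1 = f1,
       tp = tp, fn = fn, tn = tn, fp = fp)
}
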