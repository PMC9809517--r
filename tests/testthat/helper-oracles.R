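# Brute-force confusion-matrix oracle, independent of the metrics module:
# every quantity is read off an explicitly accumulated K x K table.
oracle_metrics <- function(y_true, y_pred, k = 4) {
  cm <- matrix(0, k, k)  # rows truth, cols prediction
  for (i in seq_along(y_true))
    cm[y_true[i] + 1, y_pred[i] + 1] <- cm[y_true[i] + 1, y_pred[i] + 1] + 1
  mae_c <- rep(NA_real_, k)
  for (c in 1:k) if (sum(cm[c, ]) > 0)
    mae_c[c] <- sum(cm[c, ] * abs((1:k) - c)) / sum(cm[c, ])
  P <- R <- F1 <- numeric(k)
  for (c in 1:k) {
    tp <- cm[c, c]; fp <- sum(cm[-c, c]); fn <- sum(cm[c, -c])
    P[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    R[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    F1[c] <- if (P[c] + R[c] > 0) 2 * P[c] * R[c] / (P[c] + R[c]) else 0
  }
  w <- rowSums(cm) / sum(cm)
  list(macro_mae = mean(mae_c, na.rm = TRUE),
       precision = sum(P * w), recall = sum(R * w), f1 = sum(F1 * w))
}
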