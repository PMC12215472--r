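# shared fixture builders (all generated in code; nothing stored on disk)

# a random valid M x K panel row: rows are probability vectors
random_panel_row <- function(m, k) {
  p <- matrix(stats::rexp(m * k), m, k)
  p <- p / rowSums(p)
  dimnames(p) <- list(paste0("model_", seq_len(m)),
                      paste0("class_", seq_len(k)))
  p
}

# a panel row in which every model has the stated confidence on its top
# class and spreads the rest uniformly; top classes can differ per model
row_with_confidences <- function(conf, k, top = NULL) {
  m <- length(conf)
  if (is.null(top)) top <- rep(1L, m)
  p <- matrix((1 - conf) / (k - 1), m, k)
  p[cbind(seq_len(m), top)] <- conf
  dimnames(p) <- list(paste0("model_", seq_len(m)),
                      paste0("class_", seq_len(k)))
  p
}

# small deterministic scored panel for metric tests
toy_panel <- function() {
  classes <- c("finch", "oriole", "swallow")
  probs <- array(0, c(6, 3, 2))
  # model 1: confident, mostly right; model 2: weaker
  p1 <- rbind(c(.8,.1,.1), c(.1,.8,.1), c(.1,.1,.8),
              c(.7,.2,.1), c(.2,.6,.2), c(.5,.3,.2))
  p2 <- rbind(c(.6,.2,.2), c(.3,.4,.3), c(.2,.2,.6),
              c(.3,.4,.3), c(.3,.5,.2), c(.2,.3,.5))
  probs[, , 1] <- p1; probs[, , 2] <- p2
  prediction_panel(probs, classes, c("densenet_a", "resnet_b"),
                   true_labels = c("finch", "oriole", "swallow",
                                   "finch", "oriole", "swallow"))
}

# independent brute-force Mamdani + centroid oracle (no shared code with
# infer_weights): evaluates the default-style rule base on an explicit grid
oracle_infer <- function(confidences, f, step) {
  grid <- seq(0, 1, by = step)
  sapply(names(f$outputs), function(ov) {
    agg <- rep(0, length(grid))
    for (r in f$rules) {
      if (names(r$consequent) != ov) next
      strength <- Inf
      for (v in names(r$antecedent)) {
        mf <- f$inputs[[v]]$terms[[r$antecedent[[v]]]]
        strength <- min(strength, membership_degree(mf, confidences[match(v, names(f$inputs))]))
      }
      mf_out <- f$outputs[[ov]]$terms[[r$consequent[[1]]]]
      agg <- pmax(agg, pmin(strength, membership_degree(mf_out, grid)))
    }
    if (sum(agg) <= 0) 0 else sum(grid * agg) / sum(agg)
  })
}

# definitional one-way ANOVA oracle: explicit sums of squares
oracle_anova_f <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1
  df_w <- length(all) - length(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

tiny_image_set <- function(n_classes = 2, per_class = 3, seed = 11, size = 32) {
  generate_synthetic_images(n_classes, per_class, seed = seed,
                            dir = tempfile("imgset"), size = size)
}
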