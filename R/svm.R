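# Linear SVM core shared by the pixel and object classifiers: one-vs-rest
# binary C-SVMs (e1071/libsvm, linear kernel, C = 1 by default), reduced to
# explicit weight vectors so trained models serialize to plain JSON and
# prediction is a single matrix product.

svm_ovr_train <- function(X, y, C = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes, got: ",
                            paste(levels(y), collapse = ", "))
  classes <- levels(y)
  d <- ncol(X)
  W <- matrix(0, d, length(classes))
  b <- numeric(length(classes))
  for (k in seq_along(classes)) {
    yk <- factor(ifelse(y == classes[k], "pos", "neg"),
                 levels = c("pos", "neg"))
    m <- e1071::svm(X, yk, kernel = "linear", cost = C, scale = FALSE)
    w <- as.vector(t(m$coefs) %*% m$SV)
    rho <- m$rho
    # libsvm's decision value sign refers to its internal first label;
    # orient so that positive score means "this class"
    f <- X %*% w - rho
    if (mean((f > 0) == (y == classes[k])) < 0.5) {
      w <- -w; rho <- -rho
    }
    W[, k] <- w
    b[k] <- -rho
  }
  list(classes = classes, W = W, b = b)
}

svm_ovr_predict <- function(fit, X, scores = FALSE) {
  S <- X %*% fit$W + matrix(fit$b, nrow(X), length(fit$b), byrow = TRUE)
  if (scores) return(S)
  factor(fit$classes[max.col(S, ties.method = "first")], levels = fit$classes)
}

# z-scoring with training statistics; zero-variance features pass through
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, st)
  sweep(sweep(X, 2, st$mean), 2, st$sd, "/")
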