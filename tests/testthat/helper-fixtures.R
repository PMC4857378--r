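# shared generators and independent oracles

# random invertible affine calibration model
random_model <- function() {
  repeat {
    linear <- matrix(stats::runif(4L, -2, 2), 2L, 2L)
    if (abs(det(linear)) > 0.1) break
  }
  structure(list(linear = linear, offset = stats::runif(2L, -30, 30),
                 residual_rms = 0, n_marks = 3L, family = "affine"),
            class = "calibration_model")
}

# marks data frame from a known model applied to given pixel points
marks_from_model <- function(model, P) {
  W <- t(model$linear %*% t(P)) + matrix(model$offset, nrow(P), 2L,
                                         byrow = TRUE)
  data.frame(u_px = P[, 1L], v_px = P[, 2L], x_cm = W[, 1L], y_cm = W[, 2L])
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# apply a rigid motion (+ optional uniform scale) to a 2-vector
rigid <- function(p, theta, shift, scale = 1) {
  as.numeric(scale * rotation2(theta) %*% p + shift)
}

# oracle: point-to-line distance via twice-triangle-area / base
dist_point_line <- function(p, a, b) {
  abs((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])) /
    sqrt(sum((b - a)^2))
}

# oracle: two-pass sample SD
sd_two_pass <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1L))
}

# oracle: exhaustive terminal-plateau scan
plateau_scan <- function(cv) {
  cvr <- round_half_up(cv, 2L)
  n <- length(cvr)
  for (k in 2:n) if (length(unique(cvr[k:n])) == 1L) return(k)
  NA_integer_
}
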