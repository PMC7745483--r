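make_views <- function(r = 3, t = 2, d = 3, K = 2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(K), function(k) matrix(rnorm((r + t) * d), r + t, d))
}

test_that("attention merge is the identity for a single view", {
  views <- make_views(K = 1)
  params <- dann_init(view_dim = 3, n_views = 1, hidden = c(4L), seed = 1)
  mg <- attention_merge(views, r = 3, params)
  expect_equal(mg$L, views[[1]][1:3, ], tolerance = 1e-12)
  expect_equal(mg$M, views[[1]][4:5, ], tolerance = 1e-12)
})

test_that("equal logits average the views; merged vectors stay in the hull", {
  v1 <- matrix(c(2, 0), 1)[rep(1, 3), ]
  v2 <- matrix(c(0, 2), 1)[rep(1, 3), ]
  params <- dann_init(view_dim = 2, n_views = 2, hidden = c(3L), seed = 1)
  mg <- attention_merge(list(v1, v2), r = 2, params)  # logits init at zero
  expect_equal(mg$L[1, ], c(1, 1), tolerance = 1e-12)

  # convexity: max-norm of the merged row never exceeds the view max
  views <- make_views(r = 5, t = 3, d = 4, K = 3, seed = 7)
  params <- dann_init(4, 3, hidden = c(3L), seed = 2)
  params$a_l <- rnorm(3); params$a_m <- rnorm(3)
  mg <- attention_merge(views, r = 5, params)
  for (i in 1:5) {
    cap <- max(vapply(views, function(V) max(abs(V[i, ])), 0))
    expect_lte(max(abs(mg$L[i, ])), cap + 1e-12)
  }
})

test_that("softmaxed attention weights are positive and sum to one", {
  params <- dann_init(3, 4, hidden = c(3L), seed = 3)
  params$a_l <- rnorm(4, sd = 3); params$a_m <- rnorm(4, sd = 3)
  w <- attention_weights(params)
  expect_true(all(w$lncrna > 0) && all(w$mirna > 0))
  expect_equal(sum(w$lncrna), 1, tolerance = 1e-8)
  expect_equal(sum(w$mirna), 1, tolerance = 1e-8)
})

test_that("disabling attention reproduces the unweighted sum exactly", {
  views <- make_views(r = 4, t = 3, d = 3, K = 3, seed = 5)
  params <- dann_init(3, 3, hidden = c(4L), attention = FALSE, seed = 1)
  mg <- attention_merge(views, r = 4, params)
  expect_identical(mg$L, Reduce(`+`, lapply(views, function(V) V[1:4, ])))
  expect_identical(mg$M, Reduce(`+`, lapply(views, function(V) V[5:7, ])))
})

test_that("forward pass matches a hand-rolled matrix-product oracle", {
  params <- dann_init(view_dim = 2, n_views = 1, hidden = c(4L, 3L), seed = 4)
  set.seed(9)
  F_ <- matrix(rnorm(6 * 4), 6, 4)
  out <- dann_forward(params, F_)
  # independent dense-algebra oracle
  relu <- function(x) pmax(x, 0)
  z1 <- relu(F_ %*% t(params$W[[1]]) +
               matrix(params$b[[1]], 6, 4, byrow = TRUE))
  z2 <- relu(z1 %*% t(params$W[[2]]) +
               matrix(params$b[[2]], 6, 3, byrow = TRUE))
  s <- 1 / (1 + exp(-(z2 %*% params$w_out + params$b_out)))
  expect_equal(out$score, as.numeric(s), tolerance = 1e-10)
})

test_that("all-zero weights score one half; dead ReLUs pass the bias chain", {
  params <- dann_init(2, 1, hidden = c(4L, 3L), seed = 6)
  zero <- params
  zero$W <- lapply(zero$W, function(W) W * 0)
  zero$b <- lapply(zero$b, function(b) b * 0)
  zero$w_out <- zero$w_out * 0; zero$b_out <- 0
  expect_equal(dann_forward(zero, matrix(rnorm(8), 2))$score, c(0.5, 0.5))

  dead <- params
  dead$W[[1]] <- -abs(dead$W[[1]])  # negative pre-activations on positive input
  dead$b <- lapply(dead$b, function(b) b * 0)
  dead$b_out <- 0.7
  F_pos <- matrix(abs(rnorm(8)), 2)
  expect_equal(dann_forward(dead, F_pos)$score,
               rep(1 / (1 + exp(-0.7)), 2), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  r <- 3; t_ <- 2
  views <- make_views(r = r, t = t_, d = 3, K = 2, seed = 8)
  pairs <- tidyr::expand_grid(i = seq_len(r), j = seq_len(t_))
  set.seed(10)
  labels <- rbinom(nrow(pairs), 1, 0.5)
  params <- dann_init(view_dim = 3, n_views = 2, hidden = c(4L, 3L),
                      proj_dim = 2L, seed = 11)
  # positive biases keep every ReLU unit active somewhere and away from its
  # kink, where central differences would see a spurious one-sided slope
  params$b <- lapply(params$b, function(b) b + 0.1)
  params$b_out <- 0.05

  lg <- dann_loss_grad(params, views, pairs, labels, r)
  eps <- 1e-6
  loss_at <- function(p) dann_loss_grad(p, views, pairs, labels, r)$loss
  check_field <- function(get, set, analytic) {
    vals <- get(params)
    num <- array(NA_real_, dim = dim(as.matrix(vals)) %||% length(vals))
    v <- as.numeric(vals)
    num <- v
    for (idx in seq_along(v)) {
      up <- v; up[idx] <- up[idx] + eps
      dn <- v; dn[idx] <- dn[idx] - eps
      pu <- set(params, up); pd <- set(params, dn)
      num[idx] <- (loss_at(pu) - loss_at(pd)) / (2 * eps)
    }
    a <- as.numeric(analytic)
    expect_equal(num, a, tolerance = 1e-5)
  }
  reshape_like <- function(template, v) {
    if (is.matrix(template)) matrix(v, nrow(template), ncol(template)) else v
  }
  check_field(function(p) p$a_l,
              function(p, v) { p$a_l <- v; p }, lg$grads$a_l)
  check_field(function(p) p$a_m,
              function(p, v) { p$a_m <- v; p }, lg$grads$a_m)
  check_field(function(p) p$w_out,
              function(p, v) { p$w_out <- v; p }, lg$grads$w_out)
  check_field(function(p) p$b_out,
              function(p, v) { p$b_out <- v; p }, lg$grads$b_out)
  for (l in 1:2) {
    check_field(function(p) p$W[[l]],
                function(p, v) { p$W[[l]] <- reshape_like(p$W[[l]], v); p },
                lg$grads$W[[l]])
    check_field(function(p) p$b[[l]],
                function(p, v) { p$b[[l]] <- v; p }, lg$grads$b[[l]])
  }
  for (k in 1:2) {
    check_field(function(p) p$P[[k]],
                function(p, v) { p$P[[k]] <- reshape_like(p$P[[k]], v); p },
                lg$grads$P[[k]])
  }
})

test_that("initial loss sits at chance on balanced labels and then descends", {
  r <- 6; t_ <- 5
  views <- make_views(r = r, t = t_, d = 4, K = 2, seed = 12)
  pairs <- tidyr::expand_grid(i = seq_len(r), j = seq_len(t_))
  set.seed(13)
  pairs$label <- rep_len(c(0L, 1L), nrow(pairs))
  params <- dann_init(4, 2, hidden = c(6L, 4L), seed = 14)
  lg <- dann_loss_grad(params, views, pairs, pairs$label, r)
  expect_lt(abs(lg$loss - log(2)), 0.05)

  trained <- dann_train(views, pairs, r, hidden = c(6L, 4L), epochs = 150,
                        learning_rate = 0.05, seed = 14)
  trace <- attr(trained, "loss_trace")
  expect_lt(trace[length(trace)], trace[1])
})

test_that("extracted pair features have width 2p and are deterministic in inputs", {
  r <- 4; t_ <- 3
  views <- make_views(r = r, t = t_, d = 3, K = 2, seed = 15)
  # duplicate lncRNA rows 1 and 2 in every view
  views <- lapply(views, function(V) { V[2, ] <- V[1, ]; V })
  pairs <- tidyr::expand_grid(i = seq_len(r), j = seq_len(t_))
  pairs$label <- rbinom(nrow(pairs), 1, 0.5)
  trained <- dann_train(views, pairs, r, hidden = c(4L), epochs = 30,
                        proj_dim = 2L, seed = 16)
  F_ <- extract_pair_features(views, trained, pairs, r)
  expect_equal(ncol(F_), 4)  # 2 * proj_dim
  for (jj in seq_len(t_)) {
    expect_equal(F_[pairs$i == 1 & pairs$j == jj, ],
                 F_[pairs$i == 2 & pairs$j == jj, ])
  }
})
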