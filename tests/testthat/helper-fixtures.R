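# Shared fixtures. The trained skin model is cached across test files.

.cache <- new.env(parent = emptyenv())

cached_skin_model <- function() {
  if (is.null(.cache$model)) {
    corpus <- generate_skin_corpus(20000, 20000, seed = 7)
    .cache$model <- build_skin_model(corpus$skin, corpus$nonskin)
  }
  .cache$model
}

disc_mask <- function(h, w, cy, cx, radius) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  (r - cy)^2 + (c - cx)^2 <= radius^2
}

# bright disc (~N(mu_in, sd)) on dark ground (~N(mu_out, sd))
two_gaussian_disc <- function(h = 64, w = 64, radius = 20, mu_in = 3000,
                              mu_out = 500, sd = 30, seed = 1) {
  set.seed(seed)
  disc <- disc_mask(h, w, h / 2, w / 2, radius)
  img <- matrix(stats::rnorm(h * w, mu_out, sd), h, w)
  img[disc] <- stats::rnorm(sum(disc), mu_in, sd)
  list(img = img, disc = disc)
}

# hand-built two-effective-bin skin model: colors (0,0,0) and (200,200,200)
# fall into different bins at 32 bins/channel; class counts 3:1 and 1:3
# give likelihood ratios 3 and 1/3.
toy_two_bin_model <- function() {
  dark <- matrix(0, 4, 3)
  lite <- matrix(200, 4, 3)
  build_skin_model(rbind(dark[1:3, ], lite[1, , drop = FALSE]),
                   rbind(dark[1, , drop = FALSE], lite[1:3, ]))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
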