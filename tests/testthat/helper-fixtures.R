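# Shared lazily-built objects so expensive frames are constructed once per
# test run. Everything is generated in code; no stored fixtures.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

frame64 <- function(name) {
  cached(paste0("f64_", name), function() {
    switch(name,
      sidwt = make_sidwt_frame(c(64, 64), "db4", 3),
      dwt = make_orthogonal_dwt_frame(c(64, 64), "db4", 3),
      tidct = make_tidct_frame(c(64, 64), 8)
    )
  })
}

frame16 <- function() cached("f16", function() make_sidwt_frame(c(16, 16), "db4", 2))

# Frozen default fixture: 64x64 Shepp-Logan, 40% variable-density, no noise.
fixture64 <- function() cached("fx64", function() make_fixture())

random_image <- function(shape) {
  matrix(stats::rnorm(prod(shape)) + 1i * stats::rnorm(prod(shape)),
         shape[1], shape[2])
}

random_coef <- function(D) {
  complex(real = stats::rnorm(D), imaginary = stats::rnorm(D))
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / max(sqrt(sum(Mod(b)^2)), .Machine$double.eps)
}
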