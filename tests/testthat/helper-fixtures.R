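## Shared fixtures built in code.

## three-generation, 12-member pedigree: founder couple gf/gm, their two
## children f1 (married to spouse s1) and f2 (married to s2), grandchildren
## on both sides, plus an unmarried third sibling u3
fixture_ped3gen <- function() {
  pedigree("FX",
    id        = c("gf", "gm", "f1", "s1", "f2", "s2", "u3",
                  "c11", "c12", "c21", "c22", "c23"),
    father_id = c(NA, NA, "gf", NA, "gf", NA, "gf",
                  "f1", "f1", "f2", "f2", "f2"),
    mother_id = c(NA, NA, "gm", NA, "gm", NA, "gm",
                  "s1", "s1", "s2", "s2", "s2"),
    sex       = c(1, 2, 1, 2, 2, 1, 1, 1, 2, 1, 2, 1),
    age       = c(75, 73, 50, 48, 46, 49, 44, 25, 23, 21, 20, 18))
}

## small clustered binary sample with a family random intercept
fixture_clustered_binary <- function(n_fam = 60, fam_size = 4, sd_b = 1,
                                     beta = c(-0.5, 0.8, -0.4), seed = 42) {
  set.seed(seed)
  fam <- rep(seq_len(n_fam), each = fam_size)
  n <- length(fam)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  b <- rnorm(n_fam, 0, sd_b)
  lp <- beta[1] + beta[2] * x1 + beta[3] * x2 + b[fam]
  y <- rbinom(n, 1, plogis(lp))
  list(y = y, X = cbind("(Intercept)" = 1, x1 = x1, x2 = x2), fam = fam)
}

## shared moderate-size simulated dataset for model/effect-level tests
.models_dat <- local({
  dat <- NULL
  function() {
    if (is.null(dat)) {
      cfg <- .cached_cfg("transition1", "dichotomous")
      cfg$n_families <- 800
      dat <<- simulate_dataset(cfg)
    }
    dat
  }
})

## calibrated small scenario shared across tests (cached per session)
.cached_cfg <- local({
  cache <- list()
  function(model = "transition1", exposure = "dichotomous", seed = 7,
           n = 20000) {
    key <- paste(model, exposure, seed, n)
    if (is.null(cache[[key]])) {
      cfg <- scenario_config(model, exposure, seed = seed)
      cache[[key]] <<- calibrate_intercepts(cfg, n = n)
    }
    cache[[key]]
  }
})
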