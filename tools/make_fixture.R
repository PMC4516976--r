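#!/usr/bin/env Rscript
## Builds inst/extdata/qfs_margins_synthetic.ped: a synthetic family table of
## 754 adult subjects in 223 families whose marginal counts reproduce the
## published QFS prevalence table (MetS 150/754 overall, 133/220 with and
## 17/534 without abdominal obesity; reduced HDL 332/754; hyperglycemia
## 55/741; elevated blood pressure 186/753; hypertriglyceridemia 214/754).
## Subjects are unrelated founders grouped into families; genotypes, ages and
## activity scores are arbitrary plausible values.  Fully deterministic.
set.seed(20260901)
n <- 754; n_obese <- 220

obese <- rep(0L, n); obese[sample(n, n_obese)] <- 1L
io <- which(obese == 1); in_ <- which(obese == 0)

assign_in <- function(idx, n_aff, n_na = 0) {
  out <- rep(0L, n)
  out[setdiff(seq_len(n), idx)] <- NA_integer_
  pick <- sample(idx, n_aff + n_na)
  out[pick[seq_len(n_aff)]] <- 1L
  if (n_na > 0) out[pick[n_aff + seq_len(n_na)]] <- NA_integer_
  out[idx[!idx %in% pick]] <- 0L
  out
}
two_strata <- function(aff_ob, aff_no, na_ob = 0, na_no = 0) {
  x <- rep(NA_integer_, n)
  po <- sample(io); x[po[seq_len(aff_ob)]] <- 1L
  x[po[aff_ob + seq_len(length(io) - aff_ob - na_ob)]] <- 0L
  pn <- sample(in_); x[pn[seq_len(aff_no)]] <- 1L
  x[pn[aff_no + seq_len(length(in_) - aff_no - na_no)]] <- 0L
  x
}
mets   <- two_strata(133, 17)
hdl    <- two_strata(149, 183)
glyc   <- two_strata(40, 15, na_ob = 1, na_no = 12)
bp     <- two_strata(98, 88, na_no = 1)
tg     <- two_strata(113, 101)

maf <- 0.25
dat <- data.frame(
  family_id = sprintf("F%03d", rep_len(1:223, n)),
  subject_id = sprintf("S%04d", seq_len(n)),
  father_id = "0", mother_id = "0",
  sex = sample(1:2, n, replace = TRUE, prob = c(336, 418)),
  age = sample(18:79, n, replace = TRUE),
  X = rbinom(n, 2, maf),
  E = round(rgamma(n, shape = 1.6, scale = 130)),
  Y1 = obese, Y2 = mets,
  elevated_bp = bp, hypertriglyceridemia = tg,
  reduced_hdl = hdl, hyperglycemia = glyc)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
con <- file("inst/extdata/qfs_margins_synthetic.ped", "w")
writeLines("# synthetic family table reproducing published QFS marginal prevalences; no real subject data", con)
write.table(dat, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
close(con)
cat("wrote", nrow(dat), "subjects\n")
print(round(c(mets = 100 * mean(mets), obese = 100 * mean(obese),
              mets_ob = 100 * mean(mets[io]), mets_no = 100 * mean(mets[in_]),
              hdl = 100 * mean(hdl), glyc = 100 * mean(glyc, na.rm = TRUE)), 1))
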