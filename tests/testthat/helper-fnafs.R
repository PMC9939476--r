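# shared fixtures, built in code

toy_cohort <- function() {
  cohort(fna_category = c("VI", "V", "III", "II"),
         fs_category = c("MALIGNANCY", "SUSPICIOUS", "BENIGN", "BENIGN"),
         outcome = c("MALIGNANT", "MALIGNANT", "BENIGN", "BENIGN"),
         label = "toy")
}

# a random cohort from a random (but seeded) generative configuration
random_cohort <- function(n = 300, seed = 1) {
  set.seed(seed)
  rp <- function(k) { x <- stats::rgamma(k, 1) + 0.05; x / sum(x) }
  cfg <- simulation_config(
    n = n,
    prevalence = stats::runif(1, 0.25, 0.85),
    fna_given_outcome = rbind(rp(6), rp(6)),
    fs_given_outcome = rbind(rp(4), rp(4)),
    seed = seed + 10000L)
  simulate_cohort(cfg)
}

# brute-force record-level 2x2 for a positivity set on a stage column
oracle_counts <- function(co, stage, positive) {
  col <- switch(stage, fna = "fna_category", fs = "fs_category",
                combined = "combined_category")
  pos <- as.character(co[[col]]) %in% positive
  ev <- co$outcome == "MALIGNANT"
  c(tp = sum(pos & ev), fp = sum(pos & !ev),
    fn = sum(!pos & ev), tn = sum(!pos & !ev))
}

# data.frame view with the label attribute dropped, for record-level
# equality checks across I/O round trips
plain_records <- function(co) {
  attr(co, "label") <- NULL
  as.data.frame(co)
}

metric_estimates <- function(met) {
  vapply(c("accuracy", "sensitivity", "specificity", "ppv", "npv"),
         function(m) met[[m]]$estimate, numeric(1))
}
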