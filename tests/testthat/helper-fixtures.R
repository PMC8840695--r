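# small in-code fixtures

tiny_records <- function() {
  validate_child_records(data.frame(
    child_id = c("c1", "c2", "c3"),
    cluster_id = c("A", "A", "B"),
    household_id = c("h1", "h1", "h2"),
    weight = c(1.2, 0.8, 1.0),
    altitude_m = c(1500, 1600, NA),
    hb_gdl = c(10.5, NA, 12.3),
    haz = c(-2.4, 0.3, -1.1),
    age_months = c(24, 10, 48),
    fever = c("Yes", "No", "No"),
    wealth = c("Poorer", "Middle", "Richer"),
    stringsAsFactors = FALSE
  ))
}

# two-cluster, three-child design used for likelihood oracle checks
tiny_design <- function() {
  rec <- validate_child_records(data.frame(
    child_id = paste0("c", 1:3), cluster_id = c("A", "A", "B"),
    household_id = "h", weight = 1,
    stunted = c(1L, 0L, 1L), anaemic = c(0L, 1L, 1L),
    fever = c("Yes", "No", "No"), stringsAsFactors = FALSE))
  build_stacked_design(rec, "fever")
}

# simulated cohort at modest scale for fit-level tests
small_cohort <- function(n_clusters = 60, mean_children = 6, seed = 7,
                         Sigma = make_sigma(0.6, 0.6, 0.3)) {
  truth <- default_truth(n_clusters = n_clusters,
                         mean_children = mean_children,
                         seed = seed, Sigma = Sigma)
  simulate_cohort(truth)
}

intercept_truth <- function(n_clusters, mean_children, Sigma,
                            p1 = 0.5, p2 = 0.5, seed = 1) {
  simulation_truth(
    theta1 = c("(Intercept)" = qlogis(p1)),
    theta2 = c("(Intercept)" = qlogis(p2)),
    Sigma = Sigma, n_clusters = n_clusters, mean_children = mean_children,
    marginals = list(), seed = seed)
}
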