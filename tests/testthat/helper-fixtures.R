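# Shared fixtures, built once per test run. The default reference fixture is
# a full-size simulated cohort (n = 4438, seed 7) with its trimmed ratios and
# reference table; expensive enough to share, cheap enough to build in a few
# seconds.

fixture_env <- new.env(parent = emptyenv())

default_reference_fixture <- function() {
  if (is.null(fixture_env$ref)) {
    cfg <- generator_config(seed = 7)
    cohort <- simulate_reference_cohort(cfg)
    ratios <- compute_ratios(cohort$lengths)
    trimmed <- trim_outliers(ratios)
    table <- build_reference(trimmed$retained, cohort$subjects)
    fixture_env$ref <- list(config = cfg, cohort = cohort, ratios = ratios,
                            trimmed = trimmed, table = table)
  }
  fixture_env$ref
}

# tiny hand-checkable reference table: all six groups share mean 0.889/0.822/
# 0.605 and sd 0.019/0.022/0.055 for r43mc/r53mc/r53mp
toy_reference <- function(means = c(r43mc = 0.889, r53mc = 0.822,
                                    r53mp = 0.605),
                          sds = c(r43mc = 0.019, r53mc = 0.022,
                                  r53mp = 0.055)) {
  groups <- tidyr::expand_grid(age_group = 1:6,
                               ratio = c("r43mc", "r53mc", "r53mp"))
  groups$n <- 100L
  groups$mean <- means[groups$ratio]
  groups$sd <- sds[groups$ratio]
  pooled <- tibble::tibble(ratio = names(means), n = 600L,
                           mean = unname(means), sd = unname(sds))
  structure(list(groups = groups, pooled = pooled, trim_limit = 2.25,
                 provenance = list(format = "phalanx-ref/1",
                                   input_hash = "toy", n_subjects = 600,
                                   package_version = "0.0.0")),
            class = "phalanx_reference")
}
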