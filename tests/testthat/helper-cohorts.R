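# shared fixture builders; everything is generated in code

# noise-free threshold cohort: outcome = short_axis > cut, with a gap of
# `margin` around the cut so the rule is learnable without boundary noise;
# all other features are uninformative
make_separable_cohort <- function(n = 500, cut = 8, margin = 0.5,
                                  seed = 1) {
  set.seed(seed)
  lo <- runif(ceiling(n / 2), 2, cut - margin)
  hi <- runif(floor(n / 2), cut + margin, 20)
  short_axis <- sample(c(lo, hi))
  prof <- data.frame(
    short_axis = short_axis,
    cortical_thickness = round(runif(n, 0.5, 6), 2),
    nodal_core_sign_absent = rbinom(n, 1, 0.2),
    perinodal_hyperechogenic_ring = rbinom(n, 1, 0.2),
    cortical_interruption = rbinom(n, 1, 0.2),
    echogenicity = sample(1:2, n, TRUE),
    focal_intranodal_deposit = sample(0:3, n, TRUE),
    vascular_flow_localization = sample(0:4, n, TRUE),
    cortical_thickening = sample(1:4, n, TRUE),
    vfa_pattern = sample(1:4, n, TRUE),
    cmid = sample(1:4, n, TRUE),
    shape = sample(1:3, n, TRUE),
    grouping = sample(1:3, n, TRUE),
    color_score = sample(1:4, n, TRUE)
  )
  prof$outcome <- as.integer(prof$short_axis > cut)
  us_cohort(prof)
}

# signature model with a single-leaf tree carrying a chosen label; used to
# exercise the marker screen and MMR escalation logic in isolation
make_stub_signature_model <- function(leaf_label = "MMR",
                                      leaf_risk = 0.16) {
  structure(list(
    markers = us_marker_names(),
    tree = structure(list(rpart = NULL,
                          leaves = data.frame(node = 1L,
                                              label = leaf_label,
                                              risk = leaf_risk,
                                              lo = NA_real_,
                                              hi = NA_real_, n = 10L,
                                              stringsAsFactors = FALSE),
                          where = integer(0)),
                     class = "risk_tree"),
    signature_risk = signature_published_risks(),
    covariate_list = us_covariate_names(),
    ppvs = NULL, risk_source = "published"
  ), class = "signature_model")
}

make_error_model <- function(b0, b, cutoff = 1) {
  structure(list(b0 = b0, b = b, cutoff = cutoff, flags = character(0)),
            class = "error_model")
}

# the majority-wins decision rule, written out independently of the
# implementation, used as the truth-table oracle
oracle_diagnosis <- function(rfc, stratum, signature) {
  if (signature == "MET") return("malignant")
  rbm_v <- c(low = "non", moderate = "int", high = "mal")[[stratum]]
  dt_v <- c(LMR = "non", MMR = "int", HMR = "mal")[[signature]]
  rfc_v <- if (rfc == 1) "mal" else "non"
  vs <- c(rfc_v, rbm_v, dt_v)
  if (rbm_v == "int" && dt_v == "int")
    return("indeterminate-biopsy-advised")
  dec <- vs[vs != "int"]
  if (length(dec) == 2 && dec[1] != dec[2])
    return("indeterminate-biopsy-advised")
  if (sum(dec == "mal") > sum(dec == "non")) "malignant" else
    "non-malignant"
}
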