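# Shared, lazily built fixtures. The expensive ones (synthetic cohorts with
# full feature extraction) are cached per test run so several test files
# can reuse them. All seeds fixed.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  hit <- .fixture_cache[[name]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  .fixture_cache[[name]] <- val
  val
}

# 2 h of pure N2: background-only and spindles-at-2/min versions
fx_n2_pair <- function() {
  fixture("n2_pair", function() {
    fs <- 128
    h <- hypnogram(rep("N2", 240))
    bg <- generate_eeg(h, group_spec("bg", spindle_density = 0, so_rate = 0),
                       fs = fs, seed = 2)
    sp <- generate_eeg(h, group_spec("sp", spindle_density = 2, so_rate = 0),
                       fs = fs, seed = 2)
    list(fs = fs, hyp = h, n2 = cbind(0, 240 * 30),
         background = bg, spindled = sp)
  })
}

# desk-scale two-group cohorts with extracted feature tables
fx_cohort_table <- function(kind) {
  fixture(paste0("cohort_", kind), function() {
    specs <- example_group_specs(kind)
    cohort <- generate_cohort(specs, seed = if (kind == "null") 11L else 12L)
    tab <- extract_cohort_features(cohort)
    list(cohort = cohort, tab = tab,
         x = as.matrix(tab[, feature_catalog()$name]),
         y = tab$group)
  })
}

# single complete clinical-scale recording and its 330-feature row
fx_full_recording <- function() {
  fixture("full_recording", function() {
    spec <- group_spec("demo")
    h <- generate_hypnogram(spec, 700L, seed = 7)
    eeg <- generate_eeg(h, spec, fs = 128, seed = 8)
    hd <- generate_hypnodensity(h, spec$hypnodensity_concentration, seed = 9)
    feats <- extract_all_features(h, eeg$samples, 128, hd)
    list(spec = spec, hyp = h, eeg = eeg, hd = hd, feats = feats)
  })
}

# synthetic per-set importance rankings (deterministic, no model fitting):
# each feature set gets mean ranks 1..n_set in catalog order
fx_rankings <- function() {
  cat_ <- feature_catalog()
  sets <- unique(cat_$set)
  rk <- lapply(sets, function(s) {
    nm <- cat_$name[cat_$set == s]
    stats::setNames(seq_along(nm), nm)
  })
  names(rk) <- sets
  rk
}
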