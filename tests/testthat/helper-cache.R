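# Shared expensive fixtures, computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Full phantom chain with the depth-decayed fluence (detection setting).
phantom_detection_run <- function() {
  cached("phantom_detection", run_phantom_study(pact_config(seed = 1)))
}

# Noiseless flat-fluence run for quantitative amplitude recovery.
phantom_contrast_run <- function() {
  cached("phantom_contrast",
         run_phantom_study(pact_config(seed = 1), flat_fluence = TRUE))
}

# Conditioned T1 scene (baseline tumor) with truth, one seed.
scene_t1 <- function(seed = 7) {
  cached(paste0("scene_t1_", seed), {
    sc <- make_vascular_scene(vascular_scene_spec(seed = seed))
    pm <- preprocess_map(sc$map, background_region = sc$truth$background_mask)
    list(scene = sc, map = pm)
  })
}

# Multi-seed study used by the segmentation-recovery and longitudinal
# acceptance properties: per seed, baseline (response 0) and complete
# response (response 1) scenes are conditioned and measured.
multi_seed_study <- function(seeds = 1:20) {
  cached("multi_seed_study", {
    rows <- lapply(seeds, function(s) {
      out <- list(seed = s)
      for (rf in c(0, 1)) {
        sc <- make_vascular_scene(vascular_scene_spec(seed = s,
                                                      response_fraction = rf))
        pm <- preprocess_map(sc$map,
                             background_region = sc$truth$background_mask)
        sk <- split_and_filter(extract_skeleton(pm))
        dm <- density_map(sk)
        fm <- weighted_entropy_map(pm)
        tm <- sc$truth$tumor_mask
        hm <- sc$truth$healthy_mask
        # 4 mm non-overlapping sampling tiles (above the vessel
        # correlation length, so tiles are effectively independent)
        pd <- welch_one_tailed(window_samples(dm$values, tm, 4, pm$pixel_size),
                               window_samples(dm$values, hm, 4, pm$pixel_size))$p
        pe <- welch_one_tailed(window_samples(fm$H, tm, 4, pm$pixel_size),
                               window_samples(fm$H, hm, 4, pm$pixel_size))$p
        tag <- if (rf == 0) "t1" else "t3"
        out[[paste0("p_density_", tag)]] <- pd
        out[[paste0("p_entropy_", tag)]] <- pe
        out[[paste0("mean_E_roi_", tag)]] <- mean(fm$E[tm])
        if (rf == 0) {
          seg <- suppressWarnings(segment_tumor(fm))
          out$dice <- sum(seg$mask & tm) * 2 / (sum(seg$mask) + sum(tm))
        }
      }
      as.data.frame(out)
    })
    do.call(rbind, rows)
  })
}
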