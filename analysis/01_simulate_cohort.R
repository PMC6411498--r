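#!/usr/bin/env Rscript
# Simulate the study cohort: 44 NC / 36 HT / 37 HM tube surfaces with
# dose-graded inward atrophy (0 / 0.6 / 1.2 mm at the patch centre), plus a
# matched demographics table.  Writes meshes (binary PLY), the covariate
# table, per-subject enclosed volumes, and a cohort manifest.
#
# The cohort is generated at the 30 x 20 ring resolution (the analysis grid
# downstream carries the correspondence; see the methods vignette).

library(hippomorph)

out <- file.path("results", "analysis")
dir.create(file.path(out, "meshes"), showWarnings = FALSE, recursive = TRUE)

# global_scale_sd 0.04 gives the ~12% between-subject volume spread typical
# of native-space hippocampi, so the scalar volume benchmark faces the same
# size-dominated variability as a real cohort
spec <- cohort_spec(template_args = list(n_rings = 30, n_around = 20),
                    global_scale_sd = 0.04,
                    seed = 20260923L)
cohort <- make_cohort(spec)
message(sprintf("generated %d subjects (%d regenerated after validity screen)",
                length(cohort$meshes), cohort$regenerated))

vols <- vapply(cohort$meshes, mesh_volume, numeric(1))
voltab <- data.frame(subject = vapply(cohort$meshes, `[[`, "", "id"),
                     group = cohort$labels, volume_mm3 = vols)
write.csv(voltab, file.path(out, "volumes.csv"), row.names = FALSE)

group_summary <- do.call(rbind, lapply(split(vols, cohort$labels), function(v)
  data.frame(n = length(v), mean = mean(v), sd = sd(v))))
print(round(group_summary, 1))
write.csv(cbind(group = rownames(group_summary), group_summary),
          file.path(out, "volume_group_summary.csv"), row.names = FALSE)

demo <- make_demographics(seed = 20260923L)
write.csv(demo, file.path(out, "demographics.csv"), row.names = FALSE)

for (m in cohort$meshes)
  write_mesh(m, file.path(out, "meshes", paste0(m$id, ".ply")))
write_mesh(cohort$template, file.path(out, "meshes", "template.ply"))

jsonlite::write_json(
  list(groups = as.list(table(cohort$labels)),
       effect_magnitudes = as.list(spec$effect_magnitudes),
       patch_center = spec$patch_center, patch_radius = spec$patch_radius,
       subject_variability_sd = spec$subject_variability_sd,
       vertex_noise_sd = spec$vertex_noise_sd,
       seed = spec$seed, regenerated = cohort$regenerated,
       truth_vertices = sum(cohort$truth_mask)),
  file.path(out, "cohort_manifest.json"), auto_unbox = TRUE, pretty = TRUE)

message("volumes: group means are close (the patch costs ~2-3% of volume); ",
        "the morphometric contrasts downstream are where the dose shows")
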