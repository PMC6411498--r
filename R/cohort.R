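#' Synthetic cohort specification
#'
#' Defines the generating conditions for a tube-surface cohort with a
#' spatially localized, dose-graded inward atrophy patch: per-group sizes
#' (default 44/36/37 for NC/HT/HM), the patch location and radius in the
#' generation parameter domain, the per-group inward displacement magnitudes
#' (mm, monotone non-decreasing with dose), the amplitude of smooth
#' per-subject shape variability, and the per-vertex noise level.
#'
#' @param group_sizes named integer vector (each >= 2), one entry per group.
#' @param effect_magnitudes inward displacement per group (mm), aligned with
#'   `group_sizes`, non-decreasing across dose.
#' @param patch_center (u, v) parameter coordinate of the atrophy patch.
#' @param patch_radius parameter-domain radius of the patch (> 0) along u;
#'   the angular extent is `patch_radius / patch_aspect_v`.
#' @param patch_aspect_v compression of the patch in the periodic v
#'   direction (> 1 narrows the patch angularly, keeping the dose effect
#'   from wrapping most of the circumference).
#' @param subject_variability_sd amplitude (mm, RMS) of the smooth random
#'   per-subject normal-displacement field.
#' @param global_scale_sd SD of the per-subject global size factor
#'   (lognormal, mean 1). The default 0 emulates meshes already normalized
#'   to a common (MNI-like) space; ~0.04 reproduces the native-space volume
#'   spread typical of hippocampi (volume SD near 12%).
#' @param vertex_noise_sd isotropic per-vertex noise SD (mm).
#' @param template_args arguments passed to [make_template_tube()].
#' @param subdivide Loop-subdivision passes applied to each subject mesh
#'   after deformation (0 keeps the generation resolution).
#' @param seed integer RNG seed.
#' @return An object of class `hm_cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(NC = 44L, HT = 36L, HM = 37L),
                        effect_magnitudes = c(NC = 0, HT = 0.6, HM = 1.2),
                        patch_center = c(0.45, 0),
                        patch_radius = 0.30,
                        patch_aspect_v = 1,
                        subject_variability_sd = 0.3,
                        global_scale_sd = 0,
                        vertex_noise_sd = 0.05,
                        template_args = list(),
                        subdivide = 0L,
                        seed = 1L) {
  if (any(group_sizes < 2L))
    stop("every group needs at least 2 subjects", call. = FALSE)
  if (length(effect_magnitudes) != length(group_sizes))
    stop("effect_magnitudes must align with group_sizes", call. = FALSE)
  if (is.unsorted(effect_magnitudes))
    stop("effect_magnitudes must be non-decreasing across dose groups",
         call. = FALSE)
  if (patch_radius <= 0) stop("patch_radius must be > 0", call. = FALSE)
  if (subject_variability_sd < 0 || vertex_noise_sd < 0 ||
      global_scale_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  names(effect_magnitudes) <- names(group_sizes)
  structure(list(group_sizes = stats::setNames(as.integer(group_sizes),
                                              names(group_sizes)),
                 groups = names(group_sizes),
                 effect_magnitudes = effect_magnitudes,
                 patch_center = patch_center, patch_radius = patch_radius,
                 patch_aspect_v = patch_aspect_v,
                 subject_variability_sd = subject_variability_sd,
                 global_scale_sd = global_scale_sd,
                 vertex_noise_sd = vertex_noise_sd,
                 template_args = template_args,
                 subdivide = as.integer(subdivide),
                 seed = as.integer(seed)),
            class = "hm_cohort_spec")
}

# periodic parameter-domain distance to the patch centre, with the v
# difference stretched by aspect so the patch is elliptic (narrower in v)
patch_distance <- function(uv, center, aspect_v = 1) {
  du <- uv[, 1] - center[1]
  dv <- abs(uv[, 2] - center[2])
  dv <- pmin(dv, 1 - dv)
  dv[is.na(dv)] <- 0.5  # cap centres: outside any reasonable patch
  sqrt(du^2 + (aspect_v * dv)^2)
}

# raised-cosine taper: 1 at the centre, 0 at radius, smooth at the boundary
patch_taper <- function(dist, radius) {
  w <- numeric(length(dist))
  inside <- dist < radius
  w[inside] <- 0.5 * (1 + cos(pi * dist[inside] / radius))
  w
}

# band-limited random normal-displacement field on the generation
# parameters: trigonometric harmonics up to k_max with gently decaying
# amplitudes, rescaled to an exact RMS amplitude
smooth_subject_field <- function(uv, sd_target, k_max = 4L) {
  if (sd_target <= 0) return(numeric(nrow(uv)))
  u <- uv[, 1]; v <- uv[, 2]
  v[is.na(v)] <- 0
  field <- numeric(length(u))
  for (k in 0:k_max) for (l in 0:k_max) {
    if (k == 0 && l == 0) next
    # extra weight on the l = 1 asymmetry (arch/bending) modes: these carry
    # the natural lateral variability of tube-like subcortical structures
    amp <- (1 + 1.5 * (l == 1)) / (1 + k + l)
    a <- rnorm(1, sd = amp); b <- rnorm(1, sd = amp)
    field <- field +
      (a * cos(2 * pi * l * v) + b * sin(2 * pi * l * v)) * cos(pi * k * u)
  }
  rms <- sqrt(mean(field^2))
  if (rms == 0) return(field)
  field * (sd_target / rms)
}

deform_subject <- function(template, spec, effect, subject_seed) {
  set.seed(subject_seed)
  uv <- attr(template, "uv")
  nrm <- vertex_normals(template)
  # global size factor first (patch depth stays in mm)
  scl <- if (spec$global_scale_sd > 0)
    exp(rnorm(1, 0, spec$global_scale_sd)) else 1
  ctr <- colMeans(template$vertices)
  V0 <- sweep(sweep(template$vertices, 2, ctr) * scl, 2, ctr, "+")
  smooth <- smooth_subject_field(uv, spec$subject_variability_sd)
  w <- patch_taper(patch_distance(uv, spec$patch_center, spec$patch_aspect_v),
                   spec$patch_radius)
  disp <- smooth - effect * w
  V <- V0 + disp * nrm
  if (spec$vertex_noise_sd > 0)
    V <- V + matrix(rnorm(prod(dim(V)), sd = spec$vertex_noise_sd), ncol = 3)
  m <- hm_mesh(V, template$faces)
  attr(m, "uv") <- uv
  attr(m, "ring_index") <- attr(template, "ring_index")
  m
}

# cheap validity screen: no face flipped against its pre-deformation normal,
# and no ring collapsed through the centerline
subject_valid <- function(mesh, template) {
  e1 <- function(m) m$vertices[m$faces[, 2], ] - m$vertices[m$faces[, 1], ]
  e2 <- function(m) m$vertices[m$faces[, 3], ] - m$vertices[m$faces[, 1], ]
  crossp <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n0 <- crossp(e1(template), e2(template))
  n1 <- crossp(e1(mesh), e2(mesh))
  if (any(rowSums(n0 * n1) <= 0)) return(FALSE)
  ring <- attr(template, "ring_index")
  cent <- apply_ring_centroids(mesh$vertices, ring)
  rad <- sqrt(rowSums((mesh$vertices - cent[ring, , drop = FALSE])^2))
  rad0 <- sqrt(rowSums((template$vertices -
                        apply_ring_centroids(template$vertices, ring)[ring, ])^2))
  keep <- rad0 > 1e-9  # skip cap centres
  all(rad[keep] > 0.1 * rad0[keep])
}

apply_ring_centroids <- function(V, ring) {
  cx <- tapply(V[, 1], ring, mean)
  cy <- tapply(V[, 2], ring, mean)
  cz <- tapply(V[, 3], ring, mean)
  cbind(cx, cy, cz)
}

#' Generate a synthetic tube-surface cohort
#'
#' Each subject is the template tube deformed by (i) a smooth random
#' low-frequency field along vertex normals with RMS amplitude
#' `subject_variability_sd`, (ii) an inward normal displacement of the
#' subject group's effect magnitude inside the atrophy patch, tapered to
#' zero at `patch_radius` by a raised-cosine window, and (iii) independent
#' isotropic vertex noise. Subjects failing a sampled validity screen
#' (flipped faces or collapsed rings) are regenerated from a derived
#' sub-seed; the regeneration count is recorded.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `hm_cohort`: list of meshes, group labels,
#'   the template mesh, per-template-vertex `truth_weight` and logical
#'   `truth_mask` (taper weight >= 0.5), and the generating spec.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "hm_cohort_spec"))
  targs <- utils::modifyList(list(radius_profile = tube_radius_profile()),
                             spec$template_args)
  template <- do.call(make_template_tube, targs)
  uv <- attr(template, "uv")
  w <- patch_taper(patch_distance(uv, spec$patch_center, spec$patch_aspect_v),
                   spec$patch_radius)
  truth_weight <- w
  # seeded-patch support: where the taper applies a non-negligible effect
  truth_mask <- if (any(spec$effect_magnitudes > 0)) w >= 0.05
                else rep(FALSE, length(w))
  labels <- rep(spec$groups, spec$group_sizes)
  n <- length(labels)
  meshes <- vector("list", n)
  regenerated <- 0L
  for (i in seq_len(n)) {
    eff <- spec$effect_magnitudes[[labels[i]]]
    for (attempt in 0:9) {
      sseed <- (spec$seed %% 100000L) * 10000L + i * 10L + attempt
      m <- deform_subject(template, spec, eff, sseed)
      if (subject_valid(m, template)) break
      regenerated <- regenerated + 1L
      if (attempt == 9L)
        stop("subject ", i, " failed validity screening repeatedly",
             call. = FALSE)
    }
    if (spec$subdivide > 0L)
      for (s in seq_len(spec$subdivide)) m <- loop_subdivide(m)
    m$id <- sprintf("sub-%03d", i)
    meshes[[i]] <- m
  }
  structure(list(meshes = meshes, labels = labels, template = template,
                 truth_weight = truth_weight, truth_mask = truth_mask,
                 spec = spec, regenerated = regenerated),
            class = "hm_cohort")
}

#' @export
print.hm_cohort <- function(x, ...) {
  cat(sprintf("<hm_cohort> %d subjects (%s); patch effect %s mm\n",
              length(x$meshes),
              paste(sprintf("%s=%d", x$spec$groups, x$spec$group_sizes),
                    collapse = ", "),
              paste(signif(x$spec$effect_magnitudes, 3), collapse = "/")))
  invisible(x)
}

#' Default demographic distributions for the synthetic cohort
#'
#' Per-group means and SDs for age, education, MMSE and AVLT-LTM, and male
#' probabilities, mirroring the demographically matched three-group design
#' of the study cohort (44/36/37 with near-identical means).
#'
#' @return A nested list keyed by variable then group.
#' @export
default_demographic_distributions <- function() {
  list(
    age = list(NC = c(58.6, 7.2), HT = c(57.2, 3.8), HM = c(58.4, 6.8)),
    education = list(NC = c(15.8, 2.3), HT = c(15.8, 2.4), HM = c(16.1, 2.1)),
    mmse = list(NC = c(29.7, 0.6), HT = c(29.9, 0.4), HM = c(29.6, 0.7)),
    avlt_ltm = list(NC = c(8.75, 2.95), HT = c(9.86, 2.86), HM = c(10.03, 3.07)),
    sex_male_prob = list(NC = 15 / 44, HT = 11 / 36, HM = 9 / 37)
  )
}

#' Generate a matched covariate table
#'
#' Draws per-subject age, education, MMSE, AVLT-LTM (normal with the
#' requested per-group moments) and sex (Bernoulli male probability).
#'
#' @param group_sizes named integer vector of per-group sizes.
#' @param distributions as [default_demographic_distributions()]: each
#'   continuous variable a list of `c(mean, sd)` per group; sex a list of
#'   male probabilities per group.
#' @param seed RNG seed.
#' @return A data.frame with subject id, group, age, education, sex, mmse,
#'   avlt_ltm.
#' @export
make_demographics <- function(group_sizes = c(NC = 44L, HT = 36L, HM = 37L),
                              distributions = default_demographic_distributions(),
                              seed = 1L) {
  groups <- names(group_sizes)
  probs <- unlist(distributions$sex_male_prob[groups])
  if (any(probs < 0 | probs > 1))
    stop("sex probabilities must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  rows <- lapply(groups, function(g) {
    n <- group_sizes[[g]]
    cont <- lapply(setdiff(names(distributions), "sex_male_prob"), function(v) {
      ms <- distributions[[v]][[g]]
      if (ms[2] < 0) stop("negative SD for ", v, call. = FALSE)
      rnorm(n, ms[1], ms[2])
    })
    names(cont) <- setdiff(names(distributions), "sex_male_prob")
    data.frame(group = g,
               age = cont$age, education = cont$education,
               sex = ifelse(rbinom(n, 1, distributions$sex_male_prob[[g]]) == 1,
                            "M", "F"),
               mmse = cont$mmse, avlt_ltm = cont$avlt_ltm)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject = sprintf("sub-%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
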