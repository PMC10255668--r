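test_that("visibility combines frustum, facing and occlusion tests", {
  sc <- small_scene()
  mesh <- sc$mesh
  vis <- compute_visibility(mesh, sc$camera, sc$poses[1])
  pose <- sc$poses[[1]]
  cam_pos <- -drop(t(pose$rotation) %*% pose$translation)
  dirs <- sweep(-mesh$vertices, 2, cam_pos, "+")
  dist <- sqrt(rowSums(dirs^2))
  cosang <- rowSums(mesh$normals * (dirs / dist))
  # back-facing vertices are never visible
  expect_false(any(vis$visible[cosang <= 0, 1]))
  # weights equal the cosine for visible vertices, zero otherwise
  expect_equal(vis$weight[vis$visible[, 1], 1],
               cosang[vis$visible[, 1]])
  expect_true(all(vis$weight[!vis$visible[, 1], 1] == 0))
  # the most front-facing visible vertex has weight near 1
  expect_gt(max(vis$weight[, 1]), 0.98)
  # occlusion agrees with the plain-R ray oracle on a sample
  set.seed(13)
  front <- which(cosang > 0.3)
  samp <- sample(front, 25)
  for (i in samp) {
    t_or <- ray_mesh_oracle(mesh$vertices[i, ], dirs[i, ] / dist[i],
                            mesh$vertices, mesh$faces, tmin = 1e-5)
    occluded_or <- !is.na(t_or) && t_or < dist[i] - 1e-5
    inside <- !is.na(vis$uv[[1]][i, 1]) &&
      vis$uv[[1]][i, 1] >= 0 & vis$uv[[1]][i, 1] <= 319 &
      vis$uv[[1]][i, 2] >= 0 & vis$uv[[1]][i, 2] <= 239
    expect_identical(vis$visible[i, 1], inside && !occluded_or)
  }
})

test_that("single constant-colour view paints all its visible vertices", {
  sc <- small_scene()
  mesh <- sc$mesh
  vis <- compute_visibility(mesh, sc$camera, sc$poses[1])
  img <- array(0L, dim = c(240, 320, 3))
  img[, , 1] <- 200L; img[, , 2] <- 40L; img[, , 3] <- 10L
  out <- assign_vertex_colors(mesh, list(img), vis)
  sel <- vis$visible[, 1] & vis$weight[, 1] >= 0.2
  expect_true(all(out$vertex_rgb[sel, 1] == 200L))
  expect_true(all(out$vertex_rgb[sel, 2] == 40L))
  # vertices invisible everywhere carry the sentinel
  unseen <- rowSums(vis$weight >= 0.2 & vis$visible) == 0
  expect_true(all(out$vertex_rgb[unseen, ] == 0L))
  expect_error(assign_vertex_colors(mesh, rep(list(img), 11), vis),
               "at most 10")
})

test_that("equal-weight blending averages channel-wise", {
  # two synthetic views of a single triangle facing both cameras equally
  V <- rbind(c(-0.05, 0, 0), c(0.05, 0, 0), c(0, 0, 0.08))
  mesh <- limb_mesh(V, matrix(c(1L, 2L, 3L), 1))
  cam <- camera_model()
  poses <- list(look_at_pose(c(0, -1.2, 0.03), c(0, 0, 0.03)),
                look_at_pose(c(0, -1.2, 0.03), c(0, 0, 0.03)))
  vis <- compute_visibility(mesh, cam, poses)
  imgA <- array(100L, dim = c(240, 320, 3))
  imgB <- array(0L, dim = c(240, 320, 3)); imgB[, , 1] <- 200L
  out <- assign_vertex_colors(mesh, list(imgA, imgB), vis, blend = TRUE)
  expect_true(all(out$vertex_rgb[, 1] == 150L))
  expect_true(all(out$vertex_rgb[, 2] == 50L))
})

test_that("with blending off every colour is a sample of one image", {
  sc <- small_scene()
  mesh <- sc$mesh
  poses <- sc$poses[c(1, 3)]
  vis <- compute_visibility(mesh, sc$camera, poses)
  images <- lapply(c(1, 3), function(i)
    encode_frame(sc$frames$rest[[i]]))
  out <- assign_vertex_colors(mesh, images, vis, blend = FALSE)
  check <- which(!is.na(vis$best) &
                   vis$weight[cbind(seq_len(nrow(mesh$vertices)),
                                    vis$best)] >= 0.2)
  set.seed(2)
  for (i in sample(check, 50)) {
    j <- vis$best[i]
    uv <- vis$uv[[j]][i, ]
    resampled <- thermomap3d:::bilinear_sample(images[[j]], uv[1], uv[2])
    expect_equal(out$vertex_rgb[i, ],
                 as.integer(floor(resampled + 0.5)),
                 ignore_attr = TRUE)
  }
})

test_that("decoded vertex temperatures reproduce the colour they carry", {
  sc <- small_scene()
  mesh <- sc$mesh
  model <- train_inverse_model(ramp_color_table(), split_seed = 1)
  mesh$vertex_rgb <- encode_temperature(rep(31, nrow(mesh$vertices)))
  out <- colors_to_temperatures(mesh, model)
  expect_equal(out$vertex_temperature,
               rep(31, nrow(mesh$vertices)), tolerance = 9 / 256)
  # sentinel vertices become NA
  mesh$vertex_rgb[1:4, ] <- 0L
  out2 <- colors_to_temperatures(mesh, model)
  expect_true(all(is.na(out2$vertex_temperature[1:4])))
  expect_error(colors_to_temperatures(sc$mesh, model), "no vertex colours")
})
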