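# legeit — boundary-attention adversarial post-processing for leg EIT

Electrical impedance tomography (EIT) reconstructs the conductivity map of
a body section from boundary voltages measured while small currents are
driven through surface electrodes. The inverse problem is severely
ill-posed: model-based reconstructions of the leg — skin, subcutaneous fat,
muscle, tibia/fibula, vessels, nerves, and possible lesions — are blurred
and artifact-laden. `legeit` implements a complete two-stage pipeline for
simulated leg EIT:

1. **Simulation**: randomized multi-tissue leg phantoms on a 64 × 64 grid
   (conductivities in [0, 2] S/m at 1 kHz reference values) and a
   finite-element sensitivity-matrix forward model for the 16-electrode
   adjacent-drive/adjacent-measurement protocol (208 voltages per frame),
   with Gaussian noise injected at an exact SNR
   (`SNR = 10·log10(RMS(V)/RMS(N))`).
2. **Reconstruction**: a hybrid total-variation (HTV) pre-reconstruction

       argmin_s ||dv − J s||² + α ||L s||² + β ||s||₁

   (`L` the diagonal Noser matrix from the column norms of `J`), solved by
   majorize–minimize IRLS, followed by a learned post-processor: a
   boundary-attention recurrent-residual U-Net (BAM-R2UNet) trained as a
   conditional Wasserstein GAN with gradient penalty under a six-term
   leg-anatomy prior loss

       L_total = 100·L_pix + 30·L_edge + 20·L_layer + 5·L_tv + 10·L_ssim + 2·L_hist.

The attention module fuses spatial attention, channel attention and a
learnable Laplacian edge map as `BN(α·x·(1+Ms)·Mc + β·x + γ·Me·x)` with
trainable scalars initialized 0.5/0.3/0.2. The network layers,
backpropagation (including double-backprop for the gradient penalty and an
analytic windowed-SSIM gradient) and the Adam/cosine-annealing optimizer are
implemented inside the package with C++ convolution kernels — no external
deep-learning runtime.

## A worked example

```r
library(legeit)

sens <- build_sensitivity()                      # FEM Jacobian, 208 x 2828
ds   <- eit_dataset(48, base_seed = 100, sens = sens)   # phantoms -> voltages -> HTV

metric_report(ds$htv, ds$truth, "HTV")$aggregate
#>   method condition rmse_mean   rmse_std ssim_mean   ssim_std psnr_mean  psnr_std
#> 1    HTV     clean 0.3075094 0.02813253 0.3043683 0.08019155  16.29808 0.7796297

cfg <- train_config(batch = 8L, epochs = 2L, base_channels = 8L,
                    critic_base = 16L, seed = 7)
m <- eitgan(ds, cfg)
m
#> BAM-R2UNet EIT post-processor (WGAN-GP)
#>   generator: base 8, t = 2, 822,477 parameters
#>   critic:    base 16, 174,609 parameters
#>   trained 2 epochs; best epoch 2 (val SSIM 0.0853, RMSE 0.4487)

pred <- predict(m, ds)                          # reconstructions in [0, 2]
run_experiment(m, ds, snrs = c(Inf, 45))        # HTV vs generator per SNR
```

The HTV row reports the artifact level of the model-based input (RMSE
≈ 0.31, SSIM ≈ 0.30 against the ground-truth phantoms); training then
learns the mapping from these inputs to clean conductivity maps — the tiny
two-epoch run above only begins to converge, and the package's desk-scale
study (240 samples, 4 epochs, base 8, learning rates scaled to the short
schedule) trains the generator past its HTV input on both mean SSIM and
mean RMSE. The full-size configuration
(`generator_config()` defaults: base 32, t = 2) carries ~13.0 M trainable
parameters; `resolution_summary()` tabulates parameters and MACs across the
32/48/64/96 resolution grid, and `bam_ablation_grid()` enumerates the eight
attention-branch ablation arms.

A thin command-line wrapper is installed at `inst/cli/legeit.R`
(`simulate`, `prereconstruct`, `train`, `evaluate`).

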