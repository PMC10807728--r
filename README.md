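# siftr

Signal theory, simulation and background correction for **SIFTER** pulsed
dipolar EPR spectroscopy.

## The problem

SIFTER (single-frequency technique for refocusing dipolar couplings) is a
four-pulse solid-echo experiment that measures the electron–electron
dipolar coupling between two spin labels and hence their distance
distribution on the 1.5–8 nm scale. Unlike DEER, the detected SIFTER
signal does not factor into an intramolecular form factor times a simple
exponential intermolecular background. Instead, at fixed total transverse
evolution time 2τ₀ and SIFTER time t = τ₁ − τ₂, the biradical signal
decomposes as

    V = (1−λ)·V_nm + λ·V_mod

    V_mod  = F(t)·½[B_S(τ₁,τ₂) + B_t(τ₁)B_t(τ₂)] + F(τ₁)F(τ₂)·Dτ₁τ₂·B_t(τ₁)B_t(τ₂)
    V_nm   = B_S·[1 + λK/2(1−λ)] + B_t B_t·[Dτ₁τ₂ − λK/2(1−λ)]

where F is the powder dipolar form factor (time-domain Pake signal), λ
the modulation depth, B_t the two-pulse (Hahn) echo decay, B_S(τ₁,τ₂) the
no-transfer relaxation surface measured by the SIDRE experiment (SIFTER
without the central π/2 pulse), D = ⟨Σωₙ²⟩ the summed second moment of
the intermolecular dipolar frequencies, and K = ⟨cos ω_dd(τ₁+τ₂)⟩ a
constant along a trace of fixed length. Because dynamical decoupling
makes B_S exceed B_t·B_t near τ₁ ≈ τ₂, the background multiplying the
modulation, ½[B_S + B_tB_t], differs in shape from the SIDRE trace — so
the common heuristic of dividing SIFTER by SIDRE distorts the dipolar
modulation. The correct procedure is to **fit and subtract the
unmodulated part, then divide by ½[B_S + B_tB_t]**.

`siftr` implements this signal theory end to end:

* **quantum core** — exact density-matrix propagation of up to 10
  spin-1/2 centres through ideal-pulse SIFTER/SIDRE/Hahn sequences; the
  brute-force oracle for every analytical expression above;
* **dipolar kernels** — powder-averaged F(t), the sine-product artefact
  kernel and the fixed-sum constant K, by deterministic Gauss–Legendre
  quadrature;
* **Monte-Carlo ensemble** — grand-canonical sampling of uniformly
  distributed mono-/biradicals: the two-pulse background B₂ₚ, the second
  moment D, and a numerical test of the background factorization
  assumption;
* **relaxation models** — sum-of-stretched-exponentials Hahn decays and a
  generalized-power-mean SIDRE surface with a single decoupling exponent
  ξ ≥ β, plus SSE fitting;
* **signal composition** — assembly of full mono- and biradical SIFTER
  signals with per-term breakdowns;
* **correction pipeline** — the subtraction/division procedure, the
  heuristic division schemes it replaces, and closed-loop Gaussian
  distance recovery;
* **synthetic studies** — a seeded generator emulating a two-radical-class
  (nitroxide-like / trityl-like) study at ~50 µM and several trace
  lengths, with plain-text trace file I/O and a thin CLI
  (`inst/cli/sifter-tools.R`).

## Worked example

Generate one synthetic nitroxide biradical sample (r = 3.0 ± 0.2 nm
Gaussian, λ = 0.3, D = 0.05 rad²/µs², SNR 50, τ₀ = 2.5 µs), run the full
correction, and fit the distance distribution:

```r
library(siftr)

dist <- gaussian_distribution(3.0, 0.2)
cfg <- study_config(
  samples = list(list(id = "nitroxide-bi", kind = "bi", preset = "nitroxide",
                      concentration_uM = 50, D = 0.05,
                      dist = dist, lambda = 0.3)),
  tau0 = 2.5, dt = 0.02, snr = 50, seed = 42)
ds <- generate_study(cfg)
e  <- ds[["nitroxide-bi"]][["2.5"]]

corr <- sifter_correct(e$sifter, e$sidre, e$hahn)
print(corr)
#> sifter_correction [proposed]: 251 points, tau0 = 2.5 µs
#>   lambda = 0.2868, D = 0.05263 rad^2/µs^2, masked = 0

fit <- recover_gaussian_distribution(corr)
sprintf("recovered distance: %.3f nm (true 3.000), width %.3f nm (true 0.200)",
        fit$r_mean, fit$r_sd)
#> "recovered distance: 3.005 nm (true 3.000), width 0.205 nm (true 0.200)"
```

`sifter_correct()` fits the Hahn decay with an SSE model, extracts the
decoupling exponent ξ from the SIDRE trace, fits the unmodulated part of
the SIFTER trace (robustly, down-weighting the modulated centre),
subtracts it, divides by the main-term background and returns the
recovered form factor with the fitted λ and D. `plot(corr)` shows the
recovered F(t); `compare_methods()` tabulates the proposed correction
against heuristic SIDRE division over a whole study.

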