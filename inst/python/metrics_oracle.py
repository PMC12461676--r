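"""Independent PSNR/SSIM reference used by the test suite.

Reads pairs of images from a raw float64 binary file (all test images, then
all reference images, column-major h x w each), computes scikit-image's
peak_signal_noise_ratio and structural_similarity (Wang et al. convention:
Gaussian window sigma 1.5, population covariance) and writes one CSV line
per pair: psnr,ssim.

Usage: python metrics_oracle.py <binfile> <h> <w> <npairs> <outcsv>
"""
import sys

import numpy as np
from skimage.metrics import peak_signal_noise_ratio, structural_similarity


def main():
    path, h, w, n, out = sys.argv[1:6]
    h, w, n = int(h), int(w), int(n)
    data = np.fromfile(path, dtype=np.float64)
    assert data.size == 2 * n * h * w, "unexpected payload size"
    imgs = data.reshape(2, n, w, h).transpose(0, 1, 3, 2)  # column-major per image
    with open(out, "w") as fh:
        for i in range(n):
            a, b = imgs[0, i], imgs[1, i]
            mse = np.mean((a - b) ** 2)
            p = np.inf if mse == 0 else peak_signal_noise_ratio(b, a, data_range=1.0)
            s = structural_similarity(
                a, b, data_range=1.0, gaussian_weights=True, sigma=1.5,
                use_sample_covariance=False,
            )
            fh.write(f"{float(p):.17g},{float(s):.17g}\n")


if __name__ == "__main__":
    main()
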