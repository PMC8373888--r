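region_id,region_name,hemisphere,dmn_member
1,ROI_001_L,left,0
2,ROI_002_R,right,0
3,ROI_003_L,left,0
4,ROI_004_R,right,0
5,ROI_005_L,left,0
6,ROI_006_R,right,0
7,ROI_007_L,left,0
8,ROI_008_R,right,0
9,ROI_009_L,left,0
10,ROI_010_R,right,0
11,ROI_011_L,left,0
12,ROI_012_R,right,0
13,ROI_013_L,left,0
14,ROI_014_R,right,0
15,ROI_015_L,left,0
16,ROI_016_R,right,0
17,ROI_017_L,left,0
18,ROI_018_R,right,0
19,ROI_019_L,left,0
20,ROI_020_R,right,0
21,ROI_021_L,left,0
22,ROI_022_R,right,0
23,ROI_023_L,left,0
24,ROI_024_R,right,0
25,ROI_025_L,left,0
26,ROI_026_R,right,0
27,ROI_027_L,left,0
28,ROI_028_R,right,0
29,ROI_029_L,left,0
30,ROI_030_R,right,0
31,ROI_031_L,left,0
32,ROI_032_R,right,0
33,ROI_033_L,left,0
34,ROI_034_R,right,0
35,ROI_035_L,left,0
36,ROI_036_R,right,0
37,ROI_037_L,left,0
38,ROI_038_R,right,0
39,ROI_039_L,left,0
40,ROI_040_R,right,0
41,ROI_041_L,left,0
42,ROI_042_R,right,0
43,ROI_043_L,left,0
44,ROI_044_R,right,0
45,ROI_045_L,left,0
46,ROI_046_R,right,0
47,ROI_047_L,left,0
48,ROI_048_R,right,0
49,ROI_049_L,left,0
50,ROI_050_R,right,0
51,ROI_051_L,left,0
52,ROI_052_R,right,0
53,ROI_053_L,left,0
54,ROI_054_R,right,0
55,ROI_055_L,left,0
56,ROI_056_R,right,0
57,ROI_057_L,left,0
58,ROI_058_R,right,0
59,ROI_059_L,left,0
60,ROI_060_R,right,0
61,ROI_061_L,left,0
62,ROI_062_R,right,0
63,ROI_063_L,left,0
64,ROI_064_R,right,0
65,ROI_065_L,left,0
66,ROI_066_R,right,0
67,ROI_067_L,left,0
68,ROI_068_R,right,0
69,ROI_069_L,left,0
70,ROI_070_R,right,0
71,ROI_071_L,left,0
72,ROI_072_R,right,0
73,ROI_073_L,left,0
74,ROI_074_R,right,0
75,ROI_075_L,left,0
76,ROI_076_R,right,0
77,ROI_077_L,left,0
78,ROI_078_R,right,0
79,ROI_079_L,left,0
80,ROI_080_R,right,0
81,ROI_081_L,left,1
82,ROI_082_R,right,1
83,ROI_083_L,left,1
84,ROI_084_R,right,1
85,ROI_085_L,left,1
86,ROI_086_R,right,1
87,ROI_087_L,left,1
88,ROI_088_R,right,1
89,ROI_089_L,left,0
90,ROI_090_R,right,0
91,ROI_091_L,left,0
92,ROI_092_R,right,0
93,ROI_093_L,left,0
94,ROI_094_R,right,0
95,ROI_095_L,left,0
96,ROI_096_R,right,0
97,ROI_097_L,left,0
98,ROI_098_R,right,0
99,ROI_099_L,left,0
100,ROI_100_R,right,0
101,ROI_101_L,left,0
102,ROI_102_R,right,0
103,ROI_103_L,left,0
104,ROI_104_R,right,0
105,ROI_105_L,left,0
106,ROI_106_R,right,0
107,ROI_107_L,left,0
108,ROI_108_R,right,0
109,ROI_109_L,left,0
110,ROI_110_R,right,0
111,ROI_111_L,left,0
112,ROI_112_R,right,0
113,ROI_113_L,left,0
114,ROI_114_R,right,0
115,ROI_115_L,left,0
116,ROI_116_R,right,0
117,ROI_117_L,left,0
118,ROI_118_R,right,0
119,ROI_119_L,left,0
120,ROI_120_R,right,0
121,ROI_121_L,left,0
122,ROI_122_R,right,0
123,ROI_123_L,left,0
124,ROI_124_R,right,0
125,ROI_125_L,left,0
126,ROI_126_R,right,0
127,ROI_127_L,left,0
128,ROI_128_R,right,0
129,ROI_129_L,left,0
130,ROI_130_R,right,0
131,ROI_131_L,left,0
132,ROI_132_R,right,0
133,ROI_133_L,left,0
134,ROI_134_R,right,0
135,ROI_135_L,left,1
136,ROI_136_R,right,1
137,ROI_137_L,left,1
138,ROI_138_R,right,1
139,ROI_139_L,left,1
140,ROI_140_R,right,1
141,ROI_141_L,left,1
142,ROI_142_R,right,1
143,ROI_143_L,left,1
144,ROI_144_R,right,1
145,ROI_145_L,left,1
146,ROI_146_R,right,1
147,ROI_147_L,left,0
148,ROI_148_R,right,0
149,ROI_149_L,left,0
150,ROI_150_R,right,0
151,ROI_151_L,left,0
152,ROI_152_R,right,0
153,ROI_153_L,left,0
154,ROI_154_R,right,0
155,ROI_155_L,left,0
156,ROI_156_R,right,0
157,ROI_157_L,left,0
158,ROI_158_R,right,0
159,ROI_159_L,left,0
160,ROI_160_R,right,0
161,ROI_161_L,left,0
162,ROI_162_R,right,0
163,ROI_163_L,left,0
164,ROI_164_R,right,0
165,ROI_165_L,left,0
166,ROI_166_R,right,0
167,ROI_167_L,left,0
168,ROI_168_R,right,0
169,ROI_169_L,left,0
170,ROI_170_R,right,0
171,ROI_171_L,left,0
172,ROI_172_R,right,0
173,ROI_173_L,left,0
174,ROI_174_R,right,0
175,ROI_175_L,left,1
176,ROI_176_R,right,1
177,ROI_177_L,left,1
178,ROI_178_R,right,1
179,ROI_179_L,left,1
180,ROI_180_R,right,1
181,ROI_181_L,left,1
182,ROI_182_R,right,1
183,ROI_183_L,left,1
184,ROI_184_R,right,1
185,ROI_185_L,left,1
186,ROI_186_R,right,1
187,ROI_187_L,left,1
188,ROI_188_R,right,1
189,ROI_189_L,left,0
190,ROI_190_R,right,0
191,ROI_191_L,left,0
192,ROI_192_R,right,0
193,ROI_193_L,left,0
194,ROI_194_R,right,0
195,ROI_195_L,left,0
196,ROI_196_R,right,0
197,ROI_197_L,left,0
198,ROI_198_R,right,0
199,ROI_199_L,left,0
200,ROI_200_R,right,0
201,ROI_201_L,left,0
202,ROI_202_R,right,0
203,ROI_203_L,left,0
204,ROI_204_R,right,0
205,ROI_205_L,left,0
206,ROI_206_R,right,0
207,ROI_207_L,left,0
208,ROI_208_R,right,0
209,ROI_209_L,left,0
210,ROI_210_R,right,0
211,ROI_211_L,left,0
212,ROI_212_R,right,0
213,ROI_213_L,left,0
214,ROI_214_R,right,0
215,ROI_215_L,left,0
216,ROI_216_R,right,0
217,ROI_217_L,left,0
218,ROI_218_R,right,0
219,ROI_219_L,left,0
220,ROI_220_R,right,0
221,ROI_221_L,left,0
222,ROI_222_R,right,0
223,ROI_223_L,left,0
224,ROI_224_R,right,0
225,ROI_225_L,left,0
226,ROI_226_R,right,0
227,ROI_227_L,left,0
228,ROI_228_R,right,0
229,ROI_229_L,left,0
230,ROI_230_R,right,0
231,ROI_231_L,left,0
232,ROI_232_R,right,0
233,ROI_233_L,left,0
234,ROI_234_R,right,0
235,ROI_235_L,left,0
236,ROI_236_R,right,0
237,ROI_237_L,left,0
238,ROI_238_R,right,0
239,ROI_239_L,left,0
240,ROI_240_R,right,0
241,ROI_241_L,left,0
242,ROI_242_R,right,0
243,ROI_243_L,left,0
244,ROI_244_R,right,0
245,ROI_245_L,left,0
246,ROI_246_R,right,0
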