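Input: Started a regimen of Taxol on August 1, 2012.
Output: ['taxol', 'BEGINS-ON', 'August 1, 2012']

Input: Carboplatin was initiated on 2014-02-11.
Output: ['carboplatin', 'BEGINS-ON', '2014-02-11']

Input: First dose of gemcitabine on 3/14/2041.
Output: ['gemcitabine', 'BEGINS-ON', '3/14/2041']

Input: FOLFOX was started last Tuesday.
Output: ['folfox', 'BEGINS-ON', 'last Tuesday']

Input: Completed cisplatin on 2015-09-30.
Output: ['cisplatin', 'ENDS-ON', '2015-09-30']

Input: Last dose of anastrozole : 10/18/2033.
Output: ['anastrozole', 'ENDS-ON', '10/18/2033']

Input: Tamoxifen was discontinued on June 4, 2027.
Output: ['tamoxifen', 'ENDS-ON', 'June 4, 2027']

Input: Paclitaxel was stopped yesterday.
Output: ['paclitaxel', 'ENDS-ON', 'yesterday']

Input: Received carboplatin on 2013-08-08.
Output: ['carboplatin', 'CONTAINS-1', '2013-08-08']

Input: Cycle 3 of oxaliplatin given on 11/2/2046.
Output: ['oxaliplatin', 'CONTAINS-1', '11/2/2046']

Input: Chemotherapy was administered on 2013-06-20.
Output: ['chemotherapy', 'CONTAINS-1', '2013-06-20']

Input: Ipilimumab was administered 2 weeks ago.
Output: ['ipilimumab', 'CONTAINS-1', '2 weeks ago']
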